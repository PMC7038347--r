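#' Describe a synthetic gait bout
#'
#' A gait plan fixes the activity, per-stride kinematics, and sampling rate
#' of a synthetic foot-mounted recording. Defaults follow typical adult
#' gait: full gait-cycle (stride) length/time of 1.4 m / 1.1 s walking,
#' 2.0 m / 0.8 s jogging, 2.6 m / 0.7 s running, with the stance phase
#' occupying the last 60% of a walking stride and the last 40% of jogging
#' and running strides.
#'
#' @param activity `"walk"`, `"jog"`, or `"run"`.
#' @param n_strides number of strides.
#' @param stride_length_m stride length, metres; scalar or per-stride
#'   vector. `NULL` uses the activity default.
#' @param stride_time_s stride duration, seconds; scalar or per-stride.
#' @param stance_fraction fraction of the stride spent with the foot on the
#'   ground (zero velocity); must lie in (0.1, 0.8).
#' @param headings_deg per-stride heading, degrees (recycled); heading
#'   changes are blended in during the swing phase.
#' @param rate_hz sampling rate (default 200).
#' @param lead_in_s,lead_out_s standing-still padding before/after the bout,
#'   seconds (used for gyroscope bias calibration).
#' @param pitch_range_deg sagittal foot-pitch excursion over the swing
#'   (plantar-flexion dip plus dorsiflexion peak, default 60).
#' @param stance_wiggle_deg amplitude of the small foot-flat pitch
#'   adjustments just after heel strike and just before the next toe-off;
#'   the middle of stance stays perfectly quiet.
#' @param jitter per-stride multiplicative jitter fraction on stride time
#'   and length (default 0 = deterministic plan).
#' @return An object of class `gait_plan`.
#' @export
#' @examples
#' plan <- gait_plan("walk", n_strides = 4)
#' gt <- plan_trajectory(plan)
#' gt$events
gait_plan <- function(activity = c("walk", "jog", "run"), n_strides = 20,
                      stride_length_m = NULL, stride_time_s = NULL,
                      stance_fraction = NULL, headings_deg = 0,
                      rate_hz = 200, lead_in_s = 0, lead_out_s = 0,
                      pitch_range_deg = 60, stance_wiggle_deg = 2,
                      jitter = 0) {
  activity <- match.arg(activity)
  defaults <- list(walk = c(len = 1.4, time = 1.1, stance = 0.6),
                   jog  = c(len = 2.0, time = 0.8, stance = 0.4),
                   run  = c(len = 2.6, time = 0.7, stance = 0.4))[[activity]]
  stride_length_m <- rep_len(stride_length_m %||% defaults[["len"]], n_strides)
  stride_time_s <- rep_len(stride_time_s %||% defaults[["time"]], n_strides)
  stance_fraction <- stance_fraction %||% defaults[["stance"]]
  if (stance_fraction <= 0.1 || stance_fraction >= 0.8) {
    abort("stance_fraction must lie in (0.1, 0.8)", class = "ipdr_plan_error")
  }
  if (any(stride_time_s * rate_hz < 40)) {
    abort("stride_time_s * rate_hz must be >= 40 samples",
          class = "ipdr_plan_error")
  }
  structure(list(
    activity = activity, n_strides = n_strides,
    stride_length_m = stride_length_m, stride_time_s = stride_time_s,
    stance_fraction = stance_fraction,
    headings_deg = rep_len(headings_deg, n_strides),
    rate_hz = rate_hz, lead_in_s = lead_in_s, lead_out_s = lead_out_s,
    pitch_range_deg = pitch_range_deg,
    stance_wiggle_deg = stance_wiggle_deg, jitter = jitter
  ), class = "gait_plan")
}

#' Closed-loop gait plan
#'
#' Convenience wrapper building a rectangular closed-loop plan (equal
#' strides per side, 90 degree turns), the typical evaluation course for
#' closed-loop return-position-error experiments.
#'
#' @param activity passed to [gait_plan()].
#' @param strides_per_side strides along each of the four sides.
#' @param ... further arguments to [gait_plan()].
#' @return A `gait_plan` whose final ground-truth position equals the start.
#' @export
closed_loop_plan <- function(activity = "walk", strides_per_side = 10, ...) {
  gait_plan(activity, n_strides = 4 * strides_per_side,
            headings_deg = rep(c(0, 90, 180, 270), each = strides_per_side),
            ...)
}

# sagittal foot pitch over the swing phase, u in [0, 1): a raised-cosine
# plantar-flexion dip (-a1), dorsiflexion rise to +a2, and descent back to
# flat; its rate gives gyroscope-z the stride morphology used for
# templates: small negative valley, dominant positive swing peak, negative
# peak before foot-flat.
swing_pitch <- function(u, range_rad, u1 = 0.25, u2 = 0.65) {
  a1 <- 0.25 * range_rad
  a2 <- 0.75 * range_rad
  ifelse(u < u1,
         -a1 * (1 - cos(pi * u / u1)) / 2,
         ifelse(u < u2,
                -a1 + (a1 + a2) * (1 - cos(pi * (u - u1) / (u2 - u1))) / 2,
                a2 * (1 + cos(pi * (u - u2) / (1 - u2))) / 2))
}

# foot-flat pitch adjustments: a small negative bump right after heel
# strike and a small positive bump (ending in a descent) before the next
# toe-off; the middle [0.3, 0.7] of stance is perfectly quiet.
stance_pitch <- function(v, wiggle_rad) {
  ifelse(v < 0.3, -wiggle_rad * (1 - cos(2 * pi * v / 0.3)) / 2,
         ifelse(v < 0.7, 0,
                wiggle_rad * (1 - cos(2 * pi * (v - 0.7) / 0.3)) / 2))
}

SWING_TO_FRACTION <- 0.25  # toe-off: zero-crossing before the swing peak

#' Generate the ground-truth trajectory of a gait plan
#'
#' Builds a C1 piecewise foot trajectory: flat (zero velocity) during each
#' stance window and a raised-cosine forward/lift arc during swing, with a
#' sagittal pitch oscillation whose rate reproduces the gyroscope-z stride
#' morphology. Toe-off is placed at the zero-crossing before the swing
#' peak, heel strike at the first stance sample, mid-stance at the centre
#' of the stance window.
#'
#' @param plan a [gait_plan()].
#' @param seed RNG seed, only used when `plan$jitter > 0`.
#' @return An object of class `gait_truth`: list with `samples` (tibble:
#'   `t`, positions `px py pz`, velocities `vx vy vz`, attitude `yaw pitch`
#'   in radians, logical `zv`), `events` (tibble: `stride, start, end, to,
#'   hs, ms`, 1-based sample indices), `rate_hz`, and the `plan`.
#' @export
plan_trajectory <- function(plan, seed = NULL) {
  stopifnot(inherits(plan, "gait_plan"))
  rate <- plan$rate_hz
  lens <- plan$stride_length_m
  times <- plan$stride_time_s
  if (plan$jitter > 0) {
    jit <- function(x) x * stats::runif(length(x), 1 - plan$jitter, 1 + plan$jitter)
    jittered <- if (!is.null(seed)) {
      withr::with_seed(seed, list(jit(lens), jit(times)))
    } else {
      list(jit(lens), jit(times))
    }
    lens <- jittered[[1]]
    times <- jittered[[2]]
  }
  sf <- plan$stance_fraction
  psi <- plan$headings_deg * pi / 180
  range_rad <- plan$pitch_range_deg * pi / 180
  wiggle_rad <- plan$stance_wiggle_deg * pi / 180

  n_lead <- round(plan$lead_in_s * rate)
  n_tail <- round(plan$lead_out_s * rate)

  pos <- list(); pitch <- list(); yaw <- list(); zv <- list()
  events <- vector("list", plan$n_strides)
  p0 <- c(0, 0, 0)
  offset <- n_lead
  if (n_lead > 0) {
    pos[[length(pos) + 1]] <- matrix(p0, n_lead, 3, byrow = TRUE)
    pitch[[length(pitch) + 1]] <- rep(0, n_lead)
    yaw[[length(yaw) + 1]] <- rep(psi[1], n_lead)
    zv[[length(zv) + 1]] <- rep(TRUE, n_lead)
  }
  psi_prev <- psi[1]
  for (k in seq_len(plan$n_strides)) {
    n_k <- round(times[k] * rate)
    n_sw <- round((1 - sf) * n_k)
    n_st <- n_k - n_sw
    if (n_sw < 8 || n_st < 8) {
      abort("stride too short for the sampling rate", class = "ipdr_plan_error")
    }
    u <- (seq_len(n_sw) - 1) / n_sw
    v <- (seq_len(n_st) - 1) / n_st
    dpsi <- wrap_angle(psi[k] - psi_prev)
    # attitude yaw blends in during the swing; the displacement itself is
    # along the stride's heading, so multi-stride paths close exactly
    yaw_sw <- psi_prev + dpsi * (1 - cos(pi * u)) / 2
    s <- lens[k] * (1 - cos(pi * u)) / 2
    px <- p0[1] + s * cos(psi[k])
    py <- p0[2] + s * sin(psi[k])
    lift <- 0.05 + 0.05 * match(plan$activity, c("walk", "jog", "run"))
    pz <- lift * (1 - cos(2 * pi * u)) / 2
    p_end <- c(p0[1] + lens[k] * cos(psi[k]),
               p0[2] + lens[k] * sin(psi[k]), 0)
    pos[[length(pos) + 1]] <- cbind(c(px, rep(p_end[1], n_st)),
                                    c(py, rep(p_end[2], n_st)),
                                    c(pz, rep(0, n_st)))
    pitch[[length(pitch) + 1]] <- c(swing_pitch(u, range_rad),
                                    stance_pitch(v, wiggle_rad))
    yaw[[length(yaw) + 1]] <- c(yaw_sw, rep(psi[k], n_st))
    zv[[length(zv) + 1]] <- c(rep(FALSE, n_sw + 1),
                              rep(TRUE, n_st - 1))
    events[[k]] <- tibble::tibble(
      stride = k,
      start = offset + 1L,
      end = offset + n_k,
      to = offset + round(SWING_TO_FRACTION * n_sw) + 1L,
      hs = offset + n_sw + 1L,
      ms = offset + n_sw + ceiling(n_st / 2))
    offset <- offset + n_k
    p0 <- p_end
    psi_prev <- psi[k]
  }
  if (n_tail > 0) {
    pos[[length(pos) + 1]] <- matrix(p0, n_tail, 3, byrow = TRUE)
    pitch[[length(pitch) + 1]] <- rep(0, n_tail)
    yaw[[length(yaw) + 1]] <- rep(psi_prev, n_tail)
    zv[[length(zv) + 1]] <- rep(TRUE, n_tail)
  }
  P <- do.call(rbind, pos)
  n <- nrow(P)
  dt <- 1 / rate
  V <- rbind(c(0, 0, 0), diff(P) / dt)
  samples <- tibble::tibble(
    t = (seq_len(n) - 1) * dt,
    px = P[, 1], py = P[, 2], pz = P[, 3],
    vx = V[, 1], vy = V[, 2], vz = V[, 3],
    yaw = unlist(yaw), pitch = unlist(pitch),
    zv = unlist(zv))
  structure(list(samples = samples,
                 events = dplyr::bind_rows(events),
                 rate_hz = rate, plan = plan),
            class = "gait_truth")
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("<gait_truth: %s, %d strides, %d samples @ %g Hz, %.1f m path>\n",
              x$plan$activity, nrow(x$events), nrow(x$samples), x$rate_hz,
              sum(x$plan$stride_length_m)))
  invisible(x)
}

#' Sensor noise description for synthetic IMU signals
#'
#' @param acc_noise_std accelerometer white-noise standard deviation, m/s^2.
#' @param gyr_noise_std gyroscope white-noise standard deviation, deg/s.
#' @param gyr_bias constant gyroscope bias 3-vector, deg/s.
#' @param seed integer seed making generation reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(acc_noise_std = 0, gyr_noise_std = 0,
                        gyr_bias = c(0, 0, 0), seed = 1L) {
  stopifnot(acc_noise_std >= 0, gyr_noise_std >= 0, length(gyr_bias) == 3)
  structure(list(acc_noise_std = acc_noise_std,
                 gyr_noise_std = gyr_noise_std,
                 gyr_bias = gyr_bias, seed = as.integer(seed)),
            class = "noise_model")
}

# attitude of sample i: heading yaw about nav-z, sagittal pitch about the
# (rotated) y axis, and a fixed mounting turning the mediolateral axis into
# sensor z, so the sagittal pitch rate appears on gyroscope z.
truth_attitude <- function(yaw, pitch) {
  M <- rot_x(-pi / 2)
  lapply(seq_along(yaw), function(i) rot_z(yaw[i]) %*% rot_y(pitch[i]) %*% M)
}

#' Synthesize a foot-mounted IMU recording from ground truth
#'
#' Inverse strapdown: body angular rates are exact finite differences of
#' the ground-truth attitude, and the specific force is the body-frame
#' image of the finite-difference acceleration minus gravity, so that a
#' noise-free output integrated by [strapdown_integrate()] from the true
#' initial state reproduces the ground-truth positions to machine
#' precision. Noise and bias are then added per the [noise_model()].
#'
#' @param gt a [plan_trajectory()] result.
#' @param noise a [noise_model()].
#' @return An [imu_sequence()] (activity recorded in `meta`).
#' @export
synthesize_imu <- function(gt, noise = noise_model()) {
  stopifnot(inherits(gt, "gait_truth"))
  s <- gt$samples
  n <- nrow(s)
  dt <- 1 / gt$rate_hz
  C <- truth_attitude(s$yaw, s$pitch)
  P <- cbind(s$px, s$py, s$pz)
  V <- rbind(c(0, 0, 0), diff(P) / dt)
  A <- rbind(diff(V) / dt, c(0, 0, 0))      # nav-frame acceleration at k
  g <- c(0, 0, -GRAVITY_MS2)
  w <- matrix(0, n, 3)
  f <- matrix(0, n, 3)
  for (k in seq_len(n - 1)) {
    w[k, ] <- cpp_log_so3(t(C[[k]]) %*% C[[k + 1]]) / dt
    f[k, ] <- t(C[[k]]) %*% (A[k, ] - g)
  }
  f[n, ] <- t(C[[n]]) %*% (-g)
  gyr <- w * 180 / pi
  acc <- f
  if (noise$acc_noise_std > 0 || noise$gyr_noise_std > 0) {
    noise_mats <- withr::with_seed(noise$seed, list(
      acc = matrix(rnorm(3 * n, sd = noise$acc_noise_std), n, 3),
      gyr = matrix(rnorm(3 * n, sd = noise$gyr_noise_std), n, 3)))
    acc <- acc + noise_mats$acc
    gyr <- gyr + noise_mats$gyr
  }
  gyr <- sweep(gyr, 2, noise$gyr_bias, "+")
  imu_sequence(s$t, acc, gyr, rate_hz = gt$rate_hz,
               meta = list(activity = gt$plan$activity, synthetic = TRUE))
}

#' Ground-truth initial navigation state
#'
#' The exact attitude/velocity/position at the first sample of a
#' [plan_trajectory()] result, for round-trip integration tests.
#'
#' @param gt a `gait_truth`.
#' @return A list with `C0` (3x3), `v0`, `p0`.
#' @export
truth_initial_state <- function(gt) {
  s <- gt$samples
  list(C0 = truth_attitude(s$yaw[1], s$pitch[1])[[1]],
       v0 = c(0, 0, 0), p0 = c(s$px[1], s$py[1], s$pz[1]))
}
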