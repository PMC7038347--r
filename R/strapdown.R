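#' Filter parameters for strapdown + ZUPT reconstruction
#'
#' @param sigma_a accelerometer noise, m/s^2 (default 0.01).
#' @param sigma_w gyroscope noise, rad/s (default 0.01).
#' @param sigma_v zero-velocity measurement noise, m/s (default 0.01; see
#'   [sweep_sigma_v()] for the per-trajectory selection used on closed
#'   loops).
#' @param gravity_mag gravity magnitude, m/s^2; take it from
#'   [estimate_gyro_bias()] when calibration data exist.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(sigma_a = 0.01, sigma_w = 0.01, sigma_v = 0.01,
                          gravity_mag = GRAVITY_MS2) {
  stopifnot(sigma_a > 0, sigma_w > 0, sigma_v > 0, gravity_mag > 0)
  structure(list(sigma_a = sigma_a, sigma_w = sigma_w, sigma_v = sigma_v,
                 gravity_mag = gravity_mag), class = "filter_params")
}

#' Detect zero-velocity samples
#'
#' Walking: a sample is zero-velocity when the gyroscope rate-of-turn
#' magnitude is below `threshold_dps` (default 0.6 deg/s); runs shorter
#' than `min_run` samples are discarded as chatter. Jogging/running: the
#' abrupt signal makes the magnitude rule unreliable, so the mask is true
#' exactly on a window of `half_window` samples to each side of each
#' detected mid-stance (clipped to stride bounds when supplied).
#'
#' @param seq an [imu_sequence()] (calibrated).
#' @param activity `"walk"`, `"jog"`, or `"run"`.
#' @param ms_indices mid-stance sample indices (required for jog/run).
#' @param strides optional data frame `start, end` used to clip windows.
#' @param threshold_dps gyroscope magnitude threshold, deg/s.
#' @param half_window samples to each side of mid-stance (default 5, i.e.
#'   an 11-sample window at 200 Hz).
#' @param min_run minimum run length for the walking rule (default 3).
#' @return Logical vector of length `nrow(seq)` with attribute `mode`.
#' @export
detect_zero_velocity <- function(seq, activity = c("walk", "jog", "run"),
                                 ms_indices = NULL, strides = NULL,
                                 threshold_dps = 0.6, half_window = 5L,
                                 min_run = 3L) {
  activity <- match.arg(activity)
  n <- nrow(seq)
  if (activity == "walk") {
    mag <- sqrt(seq$gx^2 + seq$gy^2 + seq$gz^2)
    mask <- mag < threshold_dps
    mask <- drop_short_runs(mask, min_run)
    return(structure(mask, mode = "gyro_threshold"))
  }
  if (is.null(ms_indices)) {
    abort("jog/run zero-velocity detection needs mid-stance indices",
          class = "ipdr_precondition_error")
  }
  mask <- rep(FALSE, n)
  for (i in seq_along(ms_indices)) {
    ms <- ms_indices[i]
    lo <- ms - half_window
    hi <- ms + half_window
    if (!is.null(strides) && nrow(strides) >= i) {
      lo <- max(lo, strides$start[i])
      hi <- min(hi, strides$end[i])
    }
    mask[max(1L, lo):min(n, hi)] <- TRUE
  }
  structure(mask, mode = "ms_window")
}

drop_short_runs <- function(mask, min_run) {
  r <- rle(mask)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

#' Strapdown inertial navigation
#'
#' First-order strapdown integration at the sampling rate: the attitude is
#' propagated from the gyroscope rates (converted to rad/s internally),
#' the accelerometer specific force is rotated into the navigation frame,
#' gravity removed, and integrated twice into velocity and position.
#' Rotation matrices are re-orthonormalized every step.
#'
#' @param seq a calibrated [imu_sequence()].
#' @param initial initial state: list with `C0` (3x3 rotation sensor to
#'   nav), `v0`, `p0`; `NULL` levels roll/pitch from the mean accelerometer
#'   over the first `level_s` seconds (yaw 0, at rest at the origin).
#' @param params a [filter_params()] (gravity magnitude is used here).
#' @param level_s seconds of data used for gravity leveling when
#'   `initial` is `NULL`.
#' @return A tibble of class `nav_history`: `t, px, py, pz, vx, vy, vz,
#'   yaw` with the attitude history in attribute `C` (3x3xn array).
#' @export
strapdown_integrate <- function(seq, initial = NULL, params = filter_params(),
                                level_s = 1) {
  run_nav(seq, initial, params, zv = NULL, level_s = level_s)
}

#' Strapdown + zero-velocity-update complementary Kalman filter
#'
#' Runs a 9-state error-state (complementary) Kalman filter alongside the
#' strapdown integration of [strapdown_integrate()]: the error state holds
#' attitude, velocity and position errors; propagation couples attitude
#' error into velocity error through the skew of the navigation-frame
#' specific force, with process noise from `sigma_a`/`sigma_w`; at every
#' zero-velocity sample the estimated velocity is measured against zero
#' with noise `sigma_v`, and the posterior error is fed back and reset.
#' With an all-false mask the output equals pure strapdown integration.
#'
#' @inheritParams strapdown_integrate
#' @param zv logical zero-velocity mask (see [detect_zero_velocity()]).
#' @return A `nav_history` tibble; attribute `cov_trace` holds the filter
#'   covariance trace before/after each update.
#' @export
zupt_kalman <- function(seq, zv, initial = NULL, params = filter_params(),
                        level_s = 1) {
  stopifnot(length(zv) == nrow(seq))
  run_nav(seq, initial, params, zv = zv, level_s = level_s)
}

run_nav <- function(seq, initial, params, zv, level_s) {
  stopifnot(inherits(params, "filter_params"))
  f <- imu_acc(seq)
  w <- imu_gyr(seq) * pi / 180
  if (any(!is.finite(f)) || any(!is.finite(w))) {
    abort("non-finite samples in the sequence", class = "ipdr_numeric_error")
  }
  rate <- imu_rate(seq)
  dt <- 1 / rate
  if (is.null(initial)) {
    n0 <- min(nrow(seq), max(2L, round(level_s * rate)))
    initial <- list(C0 = attitude_from_accel(colMeans(f[1:n0, , drop = FALSE])),
                    v0 = c(0, 0, 0), p0 = c(0, 0, 0))
  }
  g <- c(0, 0, -params$gravity_mag)
  if (is.null(zv) || !any(zv)) {
    out <- cpp_strapdown(f, w, dt, initial$C0, g)
    cov_trace <- NULL
  } else {
    out <- cpp_zupt_kalman(f, w, as.integer(zv), dt, initial$C0, g,
                           params$sigma_a, params$sigma_w, params$sigma_v)
    cov_trace <- tibble::tibble(before = out$tr_pre, after = out$tr_post)
  }
  p <- sweep(out$p, 2, initial$p0, "+") +
    outer(seq$t - seq$t[1], initial$v0)
  v <- sweep(out$v, 2, initial$v0, "+")
  yaw <- atan2(out$C[2, 1, ], out$C[1, 1, ])
  res <- tibble::tibble(t = seq$t, px = p[, 1], py = p[, 2], pz = p[, 3],
                        vx = v[, 1], vy = v[, 2], vz = v[, 3], yaw = yaw)
  structure(res, C = out$C, cov_trace = cov_trace, rate_hz = rate,
            class = c("nav_history", class(tibble::tibble())))
}

#' Select the ZUPT measurement noise on a known-endpoint trajectory
#'
#' Evaluates [zupt_kalman()] for every `sigma_v` in the grid (default
#' 0.001 to 0.05 m/s in steps of 0.001) and returns the value minimizing
#' the return position error against the known endpoint, plus the full
#' table. Ties go to the smaller `sigma_v`.
#'
#' @inheritParams zupt_kalman
#' @param known_endpoint 2-D (or 3-D; z ignored) endpoint coordinates, m.
#' @param grid `sigma_v` candidates, m/s.
#' @return List with `sigma_v` (selected) and `table` (tibble
#'   `sigma_v, rpe_m`).
#' @export
sweep_sigma_v <- function(seq, zv, known_endpoint, initial = NULL,
                          params = filter_params(),
                          grid = seq(0.001, 0.05, by = 0.001)) {
  rpe <- vapply(grid, function(sv) {
    p2 <- params
    p2$sigma_v <- sv
    nav <- zupt_kalman(seq, zv, initial = initial, params = p2)
    sqrt((nav$px[nrow(nav)] - known_endpoint[1])^2 +
         (nav$py[nrow(nav)] - known_endpoint[2])^2)
  }, numeric(1))
  best <- which(rpe == min(rpe))[1]   # ties: smaller sigma_v (grid ascending)
  list(sigma_v = grid[best],
       table = tibble::tibble(sigma_v = grid, rpe_m = rpe))
}

#' @export
autoplot.nav_history <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$px, .data$py)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (m)", y = "north (m)",
                  title = "reconstructed trajectory")
}

#' @export
glance.nav_history <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(n_samples = n, duration_s = x$t[n] - x$t[1],
                 final_x = x$px[n], final_y = x$py[n],
                 final_speed = sqrt(x$vx[n]^2 + x$vy[n]^2 + x$vz[n]^2))
}
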