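#' Estimate gyroscope bias and gravity magnitude from a standing-still interval
#'
#' The constant gyroscope bias is the per-axis mean of the gyroscope over an
#' interval in which the sensor stands still; the gravity magnitude is the
#' mean accelerometer norm over the same interval. Wearers are asked to
#' stand still for several seconds at the start of a recording precisely so
#' that this estimate is available.
#'
#' @param seq an [imu_sequence()].
#' @param static_interval integer `c(start, end)` sample interval (1-based,
#'   inclusive) known to be static; when `NULL`, auto-detected as the
#'   longest prefix whose per-axis gyroscope standard deviation stays below
#'   `max_gyro_sd_dps`.
#' @param min_static_s minimum admissible interval length, seconds
#'   (default 2).
#' @param max_gyro_sd_dps stillness ceiling: per-axis gyroscope standard
#'   deviation must stay below this (deg/s, default 1).
#' @return An object of class `imu_calibration`: list with `gyro_bias`
#'   (named 3-vector, deg/s), `gravity_mag` (m/s^2), `static_interval`.
#' @export
#' @examples
#' seq <- imu_sequence(t = (0:999) / 200,
#'                     acc = matrix(rep(c(0, 0, 9.81), each = 1000), ncol = 3),
#'                     gyr = matrix(rep(c(0.5, -0.2, 0.1), each = 1000), ncol = 3))
#' estimate_gyro_bias(seq)$gyro_bias
estimate_gyro_bias <- function(seq, static_interval = NULL,
                               min_static_s = 2, max_gyro_sd_dps = 1) {
  rate <- imu_rate(seq)
  gyr <- imu_gyr(seq)
  acc <- imu_acc(seq)
  if (is.null(static_interval)) {
    static_interval <- c(1L, longest_static_prefix(gyr, max_gyro_sd_dps))
  }
  i0 <- static_interval[1]
  i1 <- static_interval[2]
  len <- i1 - i0 + 1
  if (len < rate * min_static_s) {
    abort(sprintf(
      "static interval too short: %d samples (< %.3g s at %g Hz)",
      len, min_static_s, rate), class = "ipdr_calibration_error")
  }
  g_seg <- gyr[i0:i1, , drop = FALSE]
  sds <- apply(g_seg, 2, sd)
  if (any(sds >= max_gyro_sd_dps)) {
    abort(sprintf(
      "static interval too noisy: gyro sd (%.3g, %.3g, %.3g) deg/s exceeds %.3g",
      sds[1], sds[2], sds[3], max_gyro_sd_dps),
      class = "ipdr_calibration_error")
  }
  gravity <- mean(sqrt(rowSums(acc[i0:i1, , drop = FALSE]^2)))
  if (gravity < 9.0 || gravity > 10.5) {
    abort(sprintf(
      "mean accelerometer norm %.3f m/s^2 outside [9.0, 10.5]; interval not static or units wrong",
      gravity), class = "ipdr_calibration_error")
  }
  structure(list(
    gyro_bias = setNames(colMeans(g_seg), c("x", "y", "z")),
    gravity_mag = gravity,
    static_interval = c(start = i0, end = i1)
  ), class = "imu_calibration")
}

# largest L such that each gyro axis has sd < ceiling over samples 1..L
longest_static_prefix <- function(gyr, max_sd) {
  n <- nrow(gyr)
  k <- seq_len(n)
  ok <- rep(TRUE, n)
  for (j in 1:3) {
    x <- gyr[, j]
    cm <- cumsum(x) / k
    cs <- cumsum(x^2)
    varp <- pmax(0, (cs - k * cm^2) / pmax(1, k - 1))
    ok <- ok & sqrt(varp) < max_sd
  }
  ok[1] <- TRUE
  if (!all(ok)) max(1L, which(!ok)[1] - 1L) else n
}

#' @export
print.imu_calibration <- function(x, ...) {
  cat(sprintf(
    "<imu_calibration: bias (%.4f, %.4f, %.4f) deg/s, g = %.4f m/s^2, interval [%d, %d]>\n",
    x$gyro_bias[1], x$gyro_bias[2], x$gyro_bias[3], x$gravity_mag,
    x$static_interval[1], x$static_interval[2]))
  invisible(x)
}

#' @export
tidy.imu_calibration <- function(x, ...) {
  tibble::tibble(axis = c("x", "y", "z"),
                 gyro_bias_dps = unname(x$gyro_bias))
}

#' @export
glance.imu_calibration <- function(x, ...) {
  tibble::tibble(gravity_mag = x$gravity_mag,
                 static_start = unname(x$static_interval[1]),
                 static_end = unname(x$static_interval[2]))
}

#' Subtract an estimated gyroscope bias from a recording
#'
#' Subtracts `cal$gyro_bias` elementwise from the gyroscope channels and
#' leaves the accelerometer untouched. Applying a freshly re-estimated
#' calibration to the output changes nothing beyond the noise floor.
#'
#' @param seq an [imu_sequence()].
#' @param cal an `imu_calibration` from [estimate_gyro_bias()].
#' @return The calibrated [imu_sequence()].
#' @export
apply_calibration <- function(seq, cal) {
  stopifnot(inherits(cal, "imu_calibration"))
  seq$gx <- seq$gx - cal$gyro_bias[[1]]
  seq$gy <- seq$gy - cal$gyro_bias[[2]]
  seq$gz <- seq$gz - cal$gyro_bias[[3]]
  seq
}
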