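#' Construct an IMU sequence
#'
#' An `imu_sequence` is a tibble with columns `t` (seconds, uniform grid),
#' `ax, ay, az` (accelerometer, m/s^2) and `gx, gy, gz` (gyroscope, deg/s),
#' carrying the sampling rate and free-form provenance as attributes. It is
#' the universal input of every downstream stage. Units are fixed by
#' contract: conversion happens at load time ([read_imu()]), never
#' downstream.
#'
#' @param t numeric vector of timestamps in seconds (uniform, increasing).
#' @param acc n-by-3 matrix (or data frame) of accelerometer samples, m/s^2.
#' @param gyr n-by-3 matrix (or data frame) of gyroscope samples, deg/s.
#' @param rate_hz sampling rate in Hz; inferred from `t` when `NULL`.
#' @param meta named list of provenance (sensor id, activity label, ...).
#'
#' @return A tibble of class `imu_sequence`.
#' @export
#' @examples
#' seq <- imu_sequence(t = seq(0, 1, by = 0.005),
#'                     acc = matrix(rep(c(0, 0, 9.81), each = 201), ncol = 3),
#'                     gyr = matrix(0, 201, 3))
#' imu_rate(seq)
imu_sequence <- function(t, acc, gyr, rate_hz = NULL, meta = list()) {
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  if (length(t) < 2L) {
    abort("an imu_sequence needs at least 2 samples", class = "ipdr_data_error")
  }
  if (nrow(acc) != length(t) || nrow(gyr) != length(t) ||
      ncol(acc) != 3L || ncol(gyr) != 3L) {
    abort("acc and gyr must be n-by-3 with n == length(t)",
          class = "ipdr_data_error")
  }
  if (is.null(rate_hz)) rate_hz <- infer_rate(t)
  x <- tibble::tibble(t = as.numeric(t),
                      ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                      gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3])
  new_imu_sequence(x, rate_hz = rate_hz, meta = meta)
}

new_imu_sequence <- function(x, rate_hz, meta = list()) {
  structure(x,
            rate_hz = rate_hz,
            meta = meta,
            class = c("imu_sequence", class(tibble::tibble())))
}

#' Coerce to an IMU sequence
#'
#' @param x a data frame with columns `t, ax, ay, az, gx, gy, gz`.
#' @param rate_hz sampling rate in Hz; inferred from `t` when `NULL`.
#' @param meta named list of provenance.
#' @return A tibble of class `imu_sequence`.
#' @export
as_imu_sequence <- function(x, rate_hz = NULL, meta = list()) {
  need <- c("t", imu_channels)
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")),
          class = "ipdr_format_error")
  }
  imu_sequence(x$t, as.matrix(x[, c("ax", "ay", "az")]),
               as.matrix(x[, c("gx", "gy", "gz")]),
               rate_hz = rate_hz, meta = meta)
}

infer_rate <- function(t) {
  dt <- median(diff(t))
  if (!is.finite(dt) || dt <= 0) {
    abort("timestamps are not increasing", class = "ipdr_data_error")
  }
  r <- 1 / dt
  # snap to an integer rate when the clock is nominally integer-valued
  if (abs(r - round(r)) < 1e-3 * r) r <- round(r)
  r
}

#' @export
print.imu_sequence <- function(x, ...) {
  cat(sprintf("<imu_sequence: %d samples @ %g Hz (%.2f s)>\n",
              nrow(x), attr(x, "rate_hz"),
              nrow(x) / attr(x, "rate_hz")))
  NextMethod()
}

#' Sampling rate of an IMU sequence
#' @param x an `imu_sequence`.
#' @return Sampling rate in Hz.
#' @export
imu_rate <- function(x) attr(x, "rate_hz")

#' Accelerometer / gyroscope samples as a matrix
#' @param x an `imu_sequence`.
#' @return n-by-3 numeric matrix (m/s^2 for `imu_acc`, deg/s for `imu_gyr`).
#' @export
imu_acc <- function(x) unname(as.matrix(x[, c("ax", "ay", "az")]))

#' @rdname imu_acc
#' @export
imu_gyr <- function(x) unname(as.matrix(x[, c("gx", "gy", "gz")]))

#' Read an IMU recording from delimited text
#'
#' Reads a CSV/TSV file with a timestamp column plus six sensor channels (or
#' six channels and a declared fixed rate), converts units to the canonical
#' m/s^2 and deg/s, linearly interpolates isolated missing samples, and
#' resamples non-uniform timestamps onto a uniform grid.
#'
#' @param path file path of a delimited text file.
#' @param column_map named character (or integer) vector mapping the
#'   canonical names `t, ax, ay, az, gx, gy, gz` to columns of the file.
#'   `t` may be omitted when `rate_hz` is given. `NULL` expects canonical
#'   names (or, for headerless numeric files, the first seven columns in
#'   canonical order).
#' @param acc_unit unit of the accelerometer columns: `"m/s^2"` or `"g"`
#'   (multiplied by 9.81).
#' @param gyr_unit unit of the gyroscope columns: `"deg/s"` or `"rad/s"`.
#' @param rate_hz declared sampling rate; required when the file has no time
#'   column, otherwise inferred.
#' @param max_gap_s longest NaN run (seconds) repaired by linear
#'   interpolation; longer runs raise a data error. Default 0.1 s.
#'
#' @return An [imu_sequence()].
#' @export
read_imu <- function(path, column_map = NULL,
                     acc_unit = c("m/s^2", "g"),
                     gyr_unit = c("deg/s", "rad/s"),
                     rate_hz = NULL, max_gap_s = 0.1) {
  acc_unit <- match.arg(acc_unit)
  gyr_unit <- match.arg(gyr_unit)
  raw <- suppressMessages(
    readr::read_delim(path, delim = guess_delim(path), show_col_types = FALSE,
                      progress = FALSE)
  )
  if (!all(vapply(raw, is.numeric, logical(1)))) {
    # headerless file read with first row as names: re-read without header
    raw <- suppressMessages(
      readr::read_delim(path, delim = guess_delim(path), col_names = FALSE,
                        show_col_types = FALSE, progress = FALSE)
    )
  }
  cols <- resolve_columns(raw, column_map, need_time = is.null(rate_hz))
  has_time <- !is.na(cols[["t"]])
  n <- nrow(raw)
  t <- if (has_time) as.numeric(raw[[cols[["t"]]]]) else (seq_len(n) - 1) / rate_hz
  if (any(diff(t) <= 0)) {
    abort("timestamps are not strictly increasing", class = "ipdr_data_error")
  }
  chan <- vapply(imu_channels, function(ch) as.numeric(raw[[cols[[ch]]]]),
                 numeric(n))
  rate <- rate_hz %||% infer_rate(t)
  chan <- repair_gaps(chan, rate, max_gap_s)
  if (acc_unit == "g") chan[, 1:3] <- chan[, 1:3] * GRAVITY_MS2
  if (gyr_unit == "rad/s") chan[, 4:6] <- chan[, 4:6] * 180 / pi
  seq <- imu_sequence(t, chan[, 1:3], chan[, 4:6], rate_hz = rate,
                      meta = list(source = path))
  resample_imu(seq, rate)
}

guess_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

resolve_columns <- function(raw, column_map, need_time) {
  nm <- names(raw)
  out <- setNames(rep(NA_integer_, 7), c("t", imu_channels))
  if (is.null(column_map)) {
    if (all(c("t", imu_channels) %in% nm)) {
      for (ch in c("t", imu_channels)) out[[ch]] <- match(ch, nm)
    } else if (all(imu_channels %in% nm)) {
      for (ch in imu_channels) out[[ch]] <- match(ch, nm)
    } else if (ncol(raw) >= 7L) {
      out[] <- 1:7
    } else if (ncol(raw) == 6L && !need_time) {
      out[imu_channels] <- 1:6
    } else {
      abort("cannot resolve IMU columns; supply column_map",
            class = "ipdr_format_error")
    }
  } else {
    for (ch in names(column_map)) {
      idx <- if (is.character(column_map)) match(column_map[[ch]], nm)
             else as.integer(column_map[[ch]])
      out[[ch]] <- idx
    }
    bad <- imu_channels[is.na(out[imu_channels])]
    if (length(bad)) {
      abort(paste0("column_map is missing channels: ",
                   paste(bad, collapse = ", ")), class = "ipdr_format_error")
    }
  }
  if (need_time && is.na(out[["t"]])) {
    abort("no time column and no declared rate_hz", class = "ipdr_format_error")
  }
  as.list(out)
}

repair_gaps <- function(chan, rate_hz, max_gap_s) {
  max_run <- max(1L, floor(max_gap_s * rate_hz))
  for (j in seq_len(ncol(chan))) {
    bad <- !is.finite(chan[, j])
    if (!any(bad)) next
    r <- rle(bad)
    if (any(r$lengths[r$values] > max_run)) {
      abort(sprintf("NaN run longer than %.2g s in channel %s",
                    max_gap_s, imu_channels[j]), class = "ipdr_data_error")
    }
    idx <- seq_len(nrow(chan))
    chan[bad, j] <- approx(idx[!bad], chan[!bad, j], xout = idx[bad],
                           rule = 2)$y
  }
  chan
}

#' Resample an IMU sequence onto a uniform grid
#'
#' Linear interpolation of every channel onto `t[1] + k / rate_hz`.
#' Resampling at the native rate of an already-uniform sequence is the
#' identity.
#'
#' @param seq an [imu_sequence()].
#' @param rate_hz target sampling rate in Hz.
#' @return An [imu_sequence()] at `rate_hz`.
#' @export
resample_imu <- function(seq, rate_hz) {
  t <- seq$t
  dt <- 1 / rate_hz
  if (isTRUE(all(abs(diff(t) - dt) < 1e-9))) {
    attr(seq, "rate_hz") <- rate_hz
    return(seq)
  }
  grid <- seq(t[1], t[length(t)], by = dt)
  chan <- vapply(imu_channels, function(ch) approx(t, seq[[ch]], xout = grid)$y,
                 numeric(length(grid)))
  imu_sequence(grid, chan[, 1:3], chan[, 4:6], rate_hz = rate_hz,
               meta = attr(seq, "meta"))
}

#' Write an IMU sequence as canonical CSV
#'
#' Emits the canonical header `t,ax,ay,az,gx,gy,gz`. Values are written with
#' a fixed number of significant digits so that a save-then-load round trip
#' reproduces every sample at that precision.
#'
#' @param seq an [imu_sequence()].
#' @param path output file path.
#' @param digits significant digits written (default 9).
#' @return `path`, invisibly.
#' @export
write_imu <- function(seq, path, digits = 9) {
  df <- as.data.frame(seq)[, c("t", imu_channels)]
  txt <- vapply(df, function(x) trimws(formatC(x, digits = digits, format = "g")),
                character(nrow(df)))
  lines <- c(paste(c("t", imu_channels), collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
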