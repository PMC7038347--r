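#' Interpolate a stride to the canonical 200-sample grid
#'
#' Linear interpolation onto 200 equally spaced points spanning the full
#' stride; endpoints are preserved exactly.
#'
#' @param stride numeric vector (gyroscope-z of one stride), length >= 4.
#' @param n_out output length (canonical 200).
#' @return Numeric vector of length `n_out`.
#' @export
interpolate_stride <- function(stride, n_out = 200L) {
  if (length(stride) < 4L) {
    abort("stride shorter than 4 samples", class = "ipdr_segmentation_error")
  }
  approx(seq_along(stride), stride,
         xout = seq(1, length(stride), length.out = n_out))$y
}

#' Build a per-activity stride template
#'
#' Interpolates every labelled stride to 200 samples and averages them
#' sample by sample. Templates are stored un-normalized in deg/s; the
#' maximum absolute value is recorded as the scale constant used at match
#' time, making the segmentation threshold scale-free.
#'
#' @param strides list of numeric vectors (gyroscope-z, one per stride).
#' @param activity `"walk"`, `"jog"`, or `"run"`.
#' @return An object of class `stride_template`: list with `activity`,
#'   `samples` (length 200, deg/s), `n_source_strides`, `scale`.
#' @export
build_template <- function(strides, activity = c("walk", "jog", "run")) {
  activity <- match.arg(activity)
  if (length(strides) == 0L) {
    abort("no strides supplied", class = "ipdr_value_error")
  }
  mat <- vapply(strides, interpolate_stride, numeric(200L))
  samples <- rowMeans(mat)
  structure(list(activity = activity, samples = samples,
                 n_source_strides = length(strides),
                 scale = max(abs(samples))),
            class = "stride_template")
}

#' @export
print.stride_template <- function(x, ...) {
  cat(sprintf(
    "<stride_template: %s, 200 samples from %d strides, peak %.1f deg/s>\n",
    x$activity, x$n_source_strides, x$scale))
  invisible(x)
}

#' Write / read a stride template as JSON
#'
#' @param template a [build_template()] result.
#' @param path file path.
#' @return `write_template`: `path` invisibly; `read_template`: a
#'   `stride_template`.
#' @export
write_template <- function(template, path) {
  jsonlite::write_json(unclass(template), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(x$samples) != 200L) {
    abort("template must hold exactly 200 samples", class = "ipdr_format_error")
  }
  structure(list(activity = x$activity, samples = as.numeric(x$samples),
                 n_source_strides = as.integer(x$n_source_strides),
                 scale = as.numeric(x$scale)),
            class = "stride_template")
}

the_templates <- new.env(parent = emptyenv())

#' Default stride templates generated from synthetic gait
#'
#' Builds one template per activity from synthetic strides (20 strides per
#' activity, mild per-stride jitter, fixed seed); memoized for the session.
#' Shipped trained templates are not meaningful without their training
#' data, so the package generates its own reference waveforms.
#'
#' @return Named list of `stride_template` (walk, jog, run).
#' @export
default_templates <- function() {
  if (!is.null(the_templates$cache)) return(the_templates$cache)
  tpl <- lapply(c(walk = "walk", jog = "jog", run = "run"), function(a) {
    plan <- gait_plan(a, n_strides = 20, jitter = 0.05)
    gt <- plan_trajectory(plan, seed = 20L)
    seq <- synthesize_imu(gt, noise_model(seed = 21L))
    strides <- purrr::map2(gt$events$start, gt$events$end,
                           function(s, e) seq$gz[s:e])
    build_template(strides, a)
  })
  the_templates$cache <- tpl
  tpl
}

#' @export
autoplot.stride_template <- function(object, ...) {
  df <- tibble::tibble(sample = seq_along(object$samples),
                       gz = object$samples)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$gz)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "template sample (stride interpolated to 200)",
                  y = "gyroscope z (deg/s)",
                  title = paste0(object$activity, " stride template"))
}
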