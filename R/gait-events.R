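#' Detect toe-off within one stride
#'
#' At toe-off the gyroscope-z crosses zero as the ankle moves from plantar
#' flexion into dorsal extension. The detector anchors on the *global*
#' maximum (the swing peak) and returns the nearest zero-crossing at or
#' before it — sample `i` is a crossing when `x[i-1] <= 0 < x[i]` — which
#' makes it robust to spurious positive blips early in jogging/running
#' strides that fool a first-zero-crossing rule. When no crossing precedes
#' the maximum the stride's first index is returned with attribute
#' `low_confidence = TRUE`.
#'
#' @param stride numeric vector (gyroscope-z of one stride, deg/s).
#' @return Integer index into `stride` (attribute `low_confidence` flags a
#'   missing crossing).
#' @export
#' @examples
#' detect_toe_off(c(-1, -0.5, 0.2, 1, 3, 1, -1))  # 3
detect_toe_off <- function(stride) {
  if (all(stride <= 0)) {
    abort("no swing peak: stride has no strictly positive sample",
          class = "ipdr_event_error")
  }
  mp <- which.max(stride)
  i <- 2:mp
  crossings <- i[stride[i - 1] <= 0 & stride[i] > 0]
  if (length(crossings) == 0L) {
    return(structure(1L, low_confidence = TRUE))
  }
  structure(max(crossings), low_confidence = FALSE)
}

#' Detect mid-stance within one stride
#'
#' Interpolates the stride to 200 samples, restricts to the portion from
#' the global maximum (swing peak) to sample 160 (80% of the stride), finds
#' the minimum peak in it (heel strike), restricts again from heel strike
#' to 160, and slides 20-sample windows with 10-sample overlap; mid-stance
#' is the centre of the minimum-energy window (energy = sum of squares;
#' ties go to the earlier window), mapped back to the stride's original
#' sample coordinates. Heel strike (internal) is attached as attribute
#' `hs_idx`.
#'
#' @param stride numeric vector, length >= 40.
#' @return Integer index into `stride` (attribute `hs_idx`).
#' @export
detect_mid_stance <- function(stride) {
  n <- length(stride)
  if (n < 40L) {
    abort("stride shorter than 40 samples", class = "ipdr_event_error")
  }
  y <- interpolate_stride(stride)
  mp <- which.max(y)
  hi <- 160L
  if (mp >= hi) {
    abort("swing peak at or beyond 80% of the stride", class = "ipdr_event_error")
  }
  portion <- y[mp:hi]
  hs200 <- mp + which.min(portion) - 1L
  seg <- y[hs200:hi]
  wsize <- 20L; step <- 10L
  if (length(seg) < wsize) {
    abort("portion after heel strike shorter than one 20-sample window",
          class = "ipdr_event_error")
  }
  starts <- seq(1L, length(seg) - wsize + 1L, by = step)
  energy <- vapply(starts, function(a) sum(seg[a:(a + wsize - 1L)]^2),
                   numeric(1))
  a <- starts[which.min(energy)]
  centre200 <- hs200 + (a - 1L) + (wsize - 1L) / 2
  ms <- map_to_original(centre200, n)
  structure(ms, hs_idx = map_to_original(hs200, n))
}

# 200-grid position -> nearest original sample (inverse of the linear
# resampling grid used by interpolate_stride)
map_to_original <- function(idx200, n) {
  as.integer(round(1 + (idx200 - 1) * (n - 1) / 199))
}

#' Restitch msDTW segments into toe-off-to-toe-off strides
#'
#' Detects toe-off inside each segment, then emits strides spanning
#' consecutive toe-offs, so the stride sequence tiles the bout without
#' holes. A span longer than 2 s is truncated to its first 1.5 s (the
#' wearer is standing or sitting in between), scaled by the actual
#' sampling rate.
#'
#' @param segments a [subsequence_dtw()] result (or data frame with
#'   `start`, `end`).
#' @param signal the full gyroscope-z signal the segments index into.
#' @param rate_hz sampling rate.
#' @param max_span_s,keep_span_s truncation rule (defaults 2 s / 1.5 s).
#' @return A tibble with columns `start`, `end`, `to` (global 1-based
#'   sample indices, intervals inclusive). Zero detected toe-offs give an
#'   empty tibble.
#' @export
restitch_to_to <- function(segments, signal, rate_hz,
                           max_span_s = 2, keep_span_s = 1.5) {
  if (nrow(segments) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          to = integer(0)))
  }
  tos <- purrr::map_int(seq_len(nrow(segments)), function(i) {
    s <- segments$start[i]; e <- segments$end[i]
    idx <- tryCatch(detect_toe_off(signal[s:e]),
                    ipdr_event_error = function(cnd) NA_integer_)
    if (is.na(idx)) NA_integer_ else s + as.integer(idx) - 1L
  })
  tos <- sort(unique(tos[!is.na(tos)]))
  if (length(tos) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          to = integer(0)))
  }
  # the last toe-off opens a final stride running to the signal end (the
  # wearer's last stride has no successor); the span rule truncates it
  strides <- tibble::tibble(start = tos,
                            end = c(tos[-1] - 1L, length(signal)),
                            to = tos)
  truncate_spans(strides, rate_hz, max_span_s, keep_span_s)
}

truncate_spans <- function(strides, rate_hz, max_span_s, keep_span_s) {
  span <- strides$end - strides$start + 1L
  long <- span > max_span_s * rate_hz
  strides$end[long] <- strides$start[long] + round(keep_span_s * rate_hz) - 1L
  strides
}

#' Detect toe-off and mid-stance for every stride
#'
#' Runs [detect_toe_off()] and [detect_mid_stance()] on each stride
#' interval and returns global indices. Strides whose events cannot be
#' detected are dropped with a warning.
#'
#' @param strides data frame with `start`, `end` (e.g. [restitch_to_to()]).
#' @param signal full gyroscope-z signal.
#' @return A tibble `start, end, to, hs, ms` (global 1-based indices).
#' @export
detect_events <- function(strides, signal) {
  rows <- purrr::map(seq_len(nrow(strides)), function(i) {
    s <- strides$start[i]; e <- strides$end[i]
    x <- signal[s:e]
    out <- tryCatch({
      to <- detect_toe_off(x)
      ms <- detect_mid_stance(x)
      tibble::tibble(start = s, end = e,
                     to = s + as.integer(to) - 1L,
                     hs = s + as.integer(attr(ms, "hs_idx")) - 1L,
                     ms = s + as.integer(ms) - 1L)
    }, ipdr_event_error = function(cnd) NULL)
    out
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("event detection failed for %d stride(s); dropped", dropped))
  }
  dplyr::bind_rows(rows)
}
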