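#' Planar stride length from a position increment
#'
#' The stride length is the Euclidean norm of the planar (x, y) position
#' increment between consecutive mid-stance positions; the vertical
#' component is ignored.
#'
#' @param p_prev,p_curr 2- or 3-vectors, m.
#' @return Stride length, m.
#' @export
#' @examples
#' stride_length(c(0, 0, 0), c(3, 4, 7))  # 5
stride_length <- function(p_prev, p_curr) {
  sqrt((p_curr[1] - p_prev[1])^2 + (p_curr[2] - p_prev[2])^2)
}

#' Assemble the stride-level trajectory
#'
#' Samples the navigation solution at each mid-stance event and derives
#' per-stride planar positions, stride lengths (planar increment norms),
#' headings (atan2 of the increment) and the total travelled distance.
#' The first increment is taken from the initial position.
#'
#' @param nav a `nav_history` from [zupt_kalman()] /
#'   [strapdown_integrate()].
#' @param ms_indices mid-stance sample indices (one per stride).
#' @return A tibble of class `stride_trajectory`: `stride, x, y, sl,
#'   heading_deg`; total distance in attribute `total_distance` (also via
#'   [glance()]).
#' @export
stride_trajectory <- function(nav, ms_indices) {
  stopifnot(length(ms_indices) >= 1)
  x <- nav$px[ms_indices]
  y <- nav$py[ms_indices]
  x0 <- c(nav$px[1], x[-length(x)])
  y0 <- c(nav$py[1], y[-length(y)])
  sl <- sqrt((x - x0)^2 + (y - y0)^2)
  res <- tibble::tibble(stride = seq_along(ms_indices), x = x, y = y,
                        sl = sl,
                        heading_deg = atan2(y - y0, x - x0) * 180 / pi)
  structure(res, total_distance = sum(sl),
            class = c("stride_trajectory", class(tibble::tibble())))
}

#' @export
glance.stride_trajectory <- function(x, ...) {
  tibble::tibble(n_strides = nrow(x),
                 total_distance = attr(x, "total_distance"),
                 mean_stride_length = mean(x$sl))
}

#' @export
autoplot.stride_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stride)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (m)", y = "north (m)",
                  title = "stride positions at mid-stance")
}

#' Score detected gait events against ground truth
#'
#' An event is a true positive when it lies within `tolerance` (fraction,
#' default 0.15) of the stride's sample count from a ground-truth event;
#' matching is greedy nearest-first and one-to-one. Unmatched detections
#' are false positives, unmatched truths false negatives.
#'
#' @param detected integer sample indices of detected events.
#' @param truth integer sample indices of ground-truth events.
#' @param stride_bounds data frame `start, end`, one row per truth event
#'   (the stride each truth event belongs to); intervals must not overlap.
#' @param tolerance tolerance as a fraction of the stride length in
#'   samples (default 0.15).
#' @return A tibble of class `event_score`: `tp, fp, fn, f_score`.
#' @export
score_events <- function(detected, truth, stride_bounds, tolerance = 0.15) {
  stopifnot(length(truth) == nrow(stride_bounds))
  if (nrow(stride_bounds) > 1) {
    o <- order(stride_bounds$start)
    if (any(stride_bounds$end[o][-nrow(stride_bounds)] >=
            stride_bounds$start[o][-1])) {
      abort("stride bounds overlap", class = "ipdr_input_error")
    }
  }
  tol <- tolerance * (stride_bounds$end - stride_bounds$start + 1)
  nd <- length(detected); nt <- length(truth)
  tp <- 0L
  if (nd > 0 && nt > 0) {
    dist <- abs(outer(detected, truth, "-"))
    ok <- sweep(dist, 2, tol, "<=")
    used_d <- rep(FALSE, nd); used_t <- rep(FALSE, nt)
    ord <- order(dist)
    for (idx in ord) {
      i <- (idx - 1L) %% nd + 1L
      j <- (idx - 1L) %/% nd + 1L
      if (!ok[idx]) next
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L
      }
    }
  }
  fp <- nd - tp; fn <- nt - tp
  f <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(tibble::tibble(tp = tp, fp = fp, fn = fn, f_score = f),
            class = c("event_score", class(tibble::tibble())))
}

#' Return position error of a (closed-loop) trajectory
#'
#' Euclidean planar distance between the final stride position and the
#' known endpoint, absolute and as a percentage of the total travelled
#' distance.
#'
#' @param traj a [stride_trajectory()].
#' @param end_truth 2-D endpoint coordinates, m (the start point for a
#'   closed loop).
#' @return A tibble `rpe_m, rpe_pct` (`rpe_pct` is `NA` when the total
#'   distance is zero).
#' @export
return_position_error <- function(traj, end_truth = c(0, 0)) {
  stopifnot(nrow(traj) >= 1)
  n <- nrow(traj)
  rpe <- sqrt((traj$x[n] - end_truth[1])^2 + (traj$y[n] - end_truth[2])^2)
  total <- attr(traj, "total_distance")
  tibble::tibble(rpe_m = rpe,
                 rpe_pct = if (total > 0) 100 * rpe / total else NA_real_)
}

#' Strides out of trajectory
#'
#' Counts strides whose mid-stance position falls outside the union of the
#' admissible corridor polygons; a point on a polygon boundary counts as
#' inside.
#'
#' @param traj a [stride_trajectory()].
#' @param zones list of simple polygons, each a data frame / matrix with
#'   columns `x, y` (self-intersecting polygons are rejected).
#' @return A tibble `sot_count, sot_pct`.
#' @export
strides_out_of_trajectory <- function(traj, zones) {
  zones <- lapply(zones, function(z) {
    z <- as.data.frame(z)
    names(z)[1:2] <- c("x", "y")
    if (polygon_self_intersects(z$x, z$y)) {
      abort("self-intersecting zone polygon", class = "ipdr_input_error")
    }
    z
  })
  inside <- rep(FALSE, nrow(traj))
  for (z in zones) {
    inside <- inside |
      pracma::inpolygon(traj$x, traj$y, z$x, z$y, boundary = TRUE)
  }
  tibble::tibble(sot_count = sum(!inside),
                 sot_pct = 100 * mean(!inside))
}

# O(n^2) proper-crossing test between non-adjacent edges
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  seg_cross <- function(a, b, c, d) {
    o <- function(p, q, r) sign((q[1] - p[1]) * (r[2] - p[2]) -
                                (q[2] - p[2]) * (r[1] - p[1]))
    o(a, b, c) * o(a, b, d) < 0 && o(c, d, a) * o(c, d, b) < 0
  }
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (seg_cross(c(xs[i], ys[i]), c(xs[i + 1], ys[i + 1]),
                    c(xs[j], ys[j]), c(xs[j + 1], ys[j + 1]))) return(TRUE)
    }
  }
  FALSE
}
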