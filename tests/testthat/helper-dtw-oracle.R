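# Brute-force subsequence-matching oracle.
#
# Classic boundary-anchored DTW (cpp_dtw_lastrow: textbook recurrence,
# anchored start, no free-start row, no start propagation) is evaluated for
# every start column, giving the cost of every (start, end) window. Per end
# column this yields the minimal window cost and the set of starts
# attaining it, against which the subsequence-DP result is checked:
#   * the DP's per-end cost must equal the brute-force minimum,
#   * the DP's backtracked start must be a true argmin.
# With the Manhattan local cost, distinct starts can tie *algebraically*
# (two signal values straddling consecutive template values contribute the
# same total), so the argmin is a set; which member is reported is
# float-summation-order dependent and not a property either route can pin
# down, hence the membership check. The candidate/acceptance rule (per-end
# minimal window, threshold, length window [m/4, 2m], greedy ascending
# cost with leftmost tie-break and non-overlap discard) is then re-applied
# independently in plain R on the brute-force costs.
oracle_costs <- function(sig, tmpl) {
  scale <- max(abs(tmpl))
  ts <- matrix(tmpl / scale, ncol = 1)
  ss <- sig / scale
  n <- length(sig)
  costs <- matrix(Inf, n, n)    # [start, end]
  for (s in seq_len(n)) {
    lr <- ipdr:::cpp_dtw_lastrow(ts, matrix(ss[s:n], ncol = 1))
    costs[s, s:n] <- lr
  }
  costs
}

expect_matches_oracle <- function(sig, tmpl, threshold) {
  res <- subsequence_dtw(sig, tmpl, threshold)
  m <- length(tmpl)
  n <- length(sig)
  scale <- max(abs(tmpl))
  dp <- ipdr:::cpp_subseq_dtw(matrix(tmpl / scale, ncol = 1),
                              matrix(sig / scale, ncol = 1))
  costs <- oracle_costs(sig, tmpl)
  endcost <- apply(costs, 2, min)

  # DP last row equals the brute-force per-end minimum
  expect_equal(dp$cost, endcost, tolerance = 1e-12)
  # every DP start attains the brute-force minimum for its end
  attained <- vapply(seq_len(n), function(e) {
    costs[dp$start[e] + 1L, e] == endcost[e]
  }, logical(1))
  expect_true(all(attained))

  # independent re-application of the acceptance rule on oracle costs,
  # using the (verified optimal) starts to fix tied window extents
  start <- dp$start + 1L
  len <- seq_len(n) - start + 1L
  keep <- which(endcost <= threshold & len >= ceiling(m / 4) & len <= 2 * m)
  keep <- keep[order(endcost[keep], start[keep], keep)]
  acc <- list()
  for (e in keep) {
    s <- start[e]
    overlaps <- any(vapply(acc, function(iv) s <= iv[2] && e >= iv[1],
                           logical(1)))
    if (!overlaps) acc[[length(acc) + 1]] <- c(s, e, endcost[e])
  }
  ora <- if (length(acc) == 0) {
    tibble::tibble(start = integer(0), end = integer(0), cost = numeric(0))
  } else {
    o <- do.call(rbind, acc)
    o <- o[order(o[, 1]), , drop = FALSE]
    tibble::tibble(start = as.integer(o[, 1]), end = as.integer(o[, 2]),
                   cost = o[, 3])
  }
  expect_equal(nrow(res), nrow(ora))
  expect_equal(res$start, ora$start)
  expect_equal(res$end, ora$end)
  expect_equal(res$cost, ora$cost, tolerance = 1e-12)
  invisible(TRUE)
}

# pure-R textbook DTW used to pin the compiled classic-DTW oracle itself
dtw_reference_cost <- function(a, b) {
  m <- length(a); n <- length(b)
  D <- matrix(Inf, m + 1, n + 1)
  D[1, 1] <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1, j + 1] <- abs(a[i] - b[j]) +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  D[m + 1, n + 1]
}
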