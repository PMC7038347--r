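#include <Rcpp.h>
using namespace Rcpp;

// Subsequence DTW of a template (m x d) against a signal (n x d).
// Local cost: sum over dimensions of absolute differences.
// Step pattern (1,1), (1,0), (0,1), unweighted.  Matches may start at any
// signal column: template-row 0 carries the bare local cost (free start).
// Start columns are propagated through the DP; equal-cost predecessors
// resolve to the smallest start column (earliest tied window wins).
// Returns, per signal column j, the minimal accumulated cost of aligning
// the full template to a window ending at j, and that window's start column
// (both 0-based; the R wrapper shifts to 1-based).
// [[Rcpp::export]]
List cpp_subseq_dtw(NumericMatrix tmpl, NumericMatrix sig) {
  const int m = tmpl.nrow(), n = sig.nrow(), d = tmpl.ncol();
  std::vector<double> prev(m), cur(m);
  std::vector<int> sprev(m), scur(m);
  NumericVector cost(n);
  IntegerVector start(n);
  const double inf = R_PosInf;

  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      double c = 0.0;
      for (int k = 0; k < d; ++k) c += std::fabs(tmpl(i, k) - sig(j, k));
      if (i == 0) {
        cur[0] = c;
        scur[0] = j;
      } else {
        double diag = (j > 0) ? prev[i - 1] : inf;   // (i-1, j-1)
        double up   = (j > 0) ? prev[i]     : inf;   // (i,   j-1) horizontal
        double vert = cur[i - 1];                    // (i-1, j)   vertical
        // cost ties between predecessors keep the smallest start column,
        // so tied optimal windows resolve to their earliest start
        double best = diag;
        int s = (j > 0) ? sprev[i - 1] : 0;
        if (vert < best || (vert == best && scur[i - 1] < s)) {
          best = vert; s = scur[i - 1];
        }
        if (up < best || (up == best && sprev[i] < s)) {
          best = up; s = sprev[i];
        }
        if (j == 0) { best = vert; s = scur[i - 1]; }
        cur[i] = c + best;
        scur[i] = s;
      }
    }
    cost[j] = cur[m - 1];
    start[j] = scur[m - 1];
    std::swap(prev, cur);
    std::swap(sprev, scur);
  }
  return List::create(_["cost"] = cost, _["start"] = start);
}

// Classic boundary-anchored DTW of a template (m x d) against a signal
// prefix (n x d) whose first column is the fixed window start.  First row
// and first column of the accumulated matrix accumulate (textbook DTW).
// Returns the last row: entry j is the cost of aligning the full template
// to the window [0, j] of the supplied signal.  Used as the brute-force
// oracle against cpp_subseq_dtw (independent recurrence: anchored classic
// DTW per start column, no free-start row, no start propagation).
// [[Rcpp::export]]
NumericVector cpp_dtw_lastrow(NumericMatrix tmpl, NumericMatrix sig) {
  const int m = tmpl.nrow(), n = sig.nrow(), d = tmpl.ncol();
  std::vector<double> prev(m), cur(m);
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      double c = 0.0;
      for (int k = 0; k < d; ++k) c += std::fabs(tmpl(i, k) - sig(j, k));
      if (j == 0) {
        cur[i] = c + (i > 0 ? cur[i - 1] : 0.0);
      } else if (i == 0) {
        cur[0] = c + prev[0];
      } else {
        double best = prev[i - 1];
        if (prev[i] < best) best = prev[i];
        if (cur[i - 1] < best) best = cur[i - 1];
        cur[i] = c + best;
      }
    }
    out[j] = cur[m - 1];
    std::swap(prev, cur);
  }
  return out;
}
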