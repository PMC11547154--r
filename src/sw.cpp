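#include <Rcpp.h>
using namespace Rcpp;

// Local alignment DP over integer-encoded sequences (0 = masked/N, 1..4 = ACGT).
// Scores come from a 5x5 lookup so the caller controls complementarity vs
// identity and optional wobble pairs. Masked positions force H = 0, so no
// alignment (match, mismatch or gap move) can cross them: accepted sites from
// iterative extraction can therefore never overlap a masked footprint.
//
// Tie-breaking is fully deterministic: cell values prefer diagonal, then up
// (gap in b), then left (gap in a); among equal-scoring end cells the one
// with the smallest a index, then smallest b index, wins.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b,
                  NumericMatrix score, LogicalMatrix ismatch,
                  double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix ptr(n + 1, m + 1); // 0 stop, 1 diag, 2 up, 3 left

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int bj_ = b[j - 1];
      double h;
      int p;
      if (ai == 0 || bj_ == 0) {
        h = 0.0; p = 0;
      } else {
        const double diag = H(i - 1, j - 1) + score(ai - 1, bj_ - 1);
        const double up   = H(i - 1, j) + gap;
        const double left = H(i, j - 1) + gap;
        h = diag; p = 1;
        if (up > h)   { h = up;   p = 2; }
        if (left > h) { h = left; p = 3; }
        if (h <= 0.0) { h = 0.0;  p = 0; }
      }
      H(i, j) = h;
      ptr(i, j) = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // Traceback from the best cell.
  std::vector<int> al_a, al_b; // 0 encodes a gap
  int i = bi, j = bj, matched = 0;
  while (i > 0 && j > 0 && ptr(i, j) != 0) {
    const int p = ptr(i, j);
    if (p == 1) {
      al_a.push_back(a[i - 1]);
      al_b.push_back(b[j - 1]);
      if (ismatch(a[i - 1] - 1, b[j - 1] - 1)) ++matched;
      --i; --j;
    } else if (p == 2) {
      al_a.push_back(a[i - 1]);
      al_b.push_back(0);
      --i;
    } else {
      al_a.push_back(0);
      al_b.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(al_a.begin(), al_a.end());
  std::reverse(al_b.begin(), al_b.end());

  return List::create(
    _["score"] = best,
    _["a_start"] = i,      // 0-based start (half-open [a_start, a_end))
    _["a_end"] = bi,
    _["b_start"] = j,
    _["b_end"] = bj,
    _["matched"] = matched,
    _["aligned_a"] = IntegerVector(al_a.begin(), al_a.end()),
    _["aligned_b"] = IntegerVector(al_b.begin(), al_b.end()));
}

// Length of the longest exact common substring of two integer-encoded
// sequences; used for null calibration of spurious complementary runs.
// [[Rcpp::export]]
int longest_common_run_cpp(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] != 0 && a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else cur[j] = 0;
    }
    std::swap(prev, cur);
  }
  return best;
}
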