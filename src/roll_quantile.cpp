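#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Sliding-window quantile with edge truncation.
//
// Window for frame i (0-based) is [i - left, i + right] intersected with
// [0, n-1]; the quantile uses linear interpolation between order statistics
// (the same convention as R's quantile type 7). The window is maintained as
// an incrementally updated sorted vector: one binary-search insert and one
// binary-search erase per frame, O(n * w) memmove in the worst case, which
// is fast for the ~1000-frame windows used for fluorescence baselines.
//
// [[Rcpp::export(name = ".rollQuantileCpp")]]
NumericVector roll_quantile(NumericVector x, int left, int right, double p) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  if (left < 0 || right < 0) stop("window extents must be non-negative");
  if (p < 0.0 || p > 1.0) stop("percentile must be in [0, 1]");

  std::vector<double> win;
  win.reserve(left + right + 2);

  // prime window for frame 0: [0, min(right, n-1)]
  int hi = std::min(right, n - 1);
  for (int j = 0; j <= hi; ++j) win.push_back(x[j]);
  std::sort(win.begin(), win.end());

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      int add = i + right;       // entering frame
      int del = i - left - 1;    // leaving frame
      if (add < n) {
        std::vector<double>::iterator it =
          std::upper_bound(win.begin(), win.end(), x[add]);
        win.insert(it, x[add]);
      }
      if (del >= 0) {
        std::vector<double>::iterator it =
          std::lower_bound(win.begin(), win.end(), x[del]);
        win.erase(it);
      }
    }
    const int m = (int) win.size();
    const double h = (m - 1) * p;
    const int lo = (int) std::floor(h);
    const int up = std::min(lo + 1, m - 1);
    out[i] = win[lo] + (h - lo) * (win[up] - win[lo]);
  }
  return out;
}
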