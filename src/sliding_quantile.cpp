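#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Centered sliding-window quantile with edge truncation.
//
// At position i (0-based) the window covers indices
// [max(0, i - hl), min(n - 1, i + hr)] with hl = ceil((w-1)/2),
// hr = floor((w-1)/2), so interior windows hold exactly w samples.
// The quantile uses the type-7 definition (matches stats::quantile
// defaults), computed from a sorted buffer maintained incrementally:
// each step inserts/removes at most a handful of values by binary
// search + memmove, O(n * w) worst case but with a tiny constant.

static double type7(const std::vector<double>& s, double p) {
  const size_t m = s.size();
  if (m == 1) return s[0];
  double h = (m - 1) * p;
  size_t lo = (size_t)std::floor(h);
  if (lo >= m - 1) return s[m - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

static void sorted_insert(std::vector<double>& s, double v) {
  s.insert(std::lower_bound(s.begin(), s.end(), v), v);
}

static void sorted_erase(std::vector<double>& s, double v) {
  s.erase(std::lower_bound(s.begin(), s.end(), v));
}

// [[Rcpp::export]]
NumericVector sliding_quantile_cpp(NumericVector x, int window, double prob) {
  const int n = x.size();
  if (n == 0) return NumericVector(0);
  if (window < 1) stop("window must be >= 1");
  if (window > n) window = n;
  const int hl = (window - 1 + 1) / 2;  // ceil((w-1)/2)
  const int hr = (window - 1) / 2;      // floor((w-1)/2)

  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(window + 2);

  int lo = 0, hi = -1;  // current window [lo, hi], inclusive
  for (int i = 0; i < n; ++i) {
    int nlo = std::max(0, i - hl);
    int nhi = std::min(n - 1, i + hr);
    while (hi < nhi) sorted_insert(buf, x[++hi]);
    while (lo < nlo) sorted_erase(buf, x[lo++]);
    out[i] = type7(buf, prob);
  }
  return out;
}
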