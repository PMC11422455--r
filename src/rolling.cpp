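#include <Rcpp.h>
#include <deque>
#include <algorithm>
using namespace Rcpp;

// Peak-to-peak range (max - min) of x over a centered window of `width`
// samples; windows are truncated at the signal edges. Monotonic-deque
// sliding extrema, O(n).
// [[Rcpp::export]]
NumericVector rolling_range(NumericVector x, int width) {
  const int n = x.size();
  if (width < 1) stop("window width must be >= 1");
  const int half = (width - 1) / 2;
  NumericVector out(n);
  std::deque<int> qmax, qmin;
  int right = -1; // last index pushed into the deques
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - half);
    const int hi = std::min(n - 1, i + half);
    while (right < hi) {
      ++right;
      const double v = x[right];
      while (!qmax.empty() && x[qmax.back()] <= v) qmax.pop_back();
      qmax.push_back(right);
      while (!qmin.empty() && x[qmin.back()] >= v) qmin.pop_back();
      qmin.push_back(right);
    }
    while (qmax.front() < lo) qmax.pop_front();
    while (qmin.front() < lo) qmin.pop_front();
    out[i] = x[qmax.front()] - x[qmin.front()];
  }
  return out;
}

static double quantile_type7(std::vector<double>& w, double p) {
  // R's default (type 7) sample quantile, via partial selection.
  const int n = w.size();
  if (n == 1) return w[0];
  const double h = (n - 1) * p;
  const int lo = (int)std::floor(h);
  const double g = h - lo;
  std::nth_element(w.begin(), w.begin() + lo, w.end());
  const double xlo = w[lo];
  if (g <= 0.0) return xlo;
  const double xhi = *std::min_element(w.begin() + lo + 1, w.end());
  return xlo + g * (xhi - xlo);
}

// Type-7 quantile of x over a centered window of `width` samples (truncated
// at the edges), evaluated at 1-based indices `at`.
// [[Rcpp::export]]
NumericVector rolling_quantile_at(NumericVector x, int width, double p,
                                  IntegerVector at) {
  const int n = x.size();
  if (width < 1) stop("window width must be >= 1");
  if (p < 0.0 || p > 1.0) stop("p must be in [0, 1]");
  const int half = (width - 1) / 2;
  const int m = at.size();
  NumericVector out(m);
  std::vector<double> w;
  w.reserve(width);
  for (int k = 0; k < m; ++k) {
    const int i = at[k] - 1;
    if (i < 0 || i >= n) stop("evaluation index out of range");
    const int lo = std::max(0, i - half);
    const int hi = std::min(n - 1, i + half);
    w.assign(x.begin() + lo, x.begin() + hi + 1);
    out[k] = quantile_type7(w, p);
  }
  return out;
}
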