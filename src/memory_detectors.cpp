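// Sliding-buffer scans for the memory-based detectors. Each buffer of N
// samples is scored over all (i, j) splits; costs are O(N^2) (MBGTD) and
// O(N^3) (MBCD) per buffer, so the per-sample sweep over a full recording
// is done here rather than in R. Results match the R reference functions
// mbgtd_fom() / mbcd_fom() exactly (same arithmetic, same flooring).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector mbgtd_series(NumericVector x, int window) {
  const int t = x.size(), n = window;
  if (n < 2) stop("window must be >= 2");
  if (t < n) stop("series shorter than window");
  const int m = t - n + 1;
  NumericVector out(m);
  std::vector<double> a(n + 1), num(n + 1);
  for (int s = 0; s < m; ++s) {
    const double *buf = &x[s];
    double best = R_NegInf;
    for (int j = 2; j <= n; ++j) {
      // a[k] = sum_{l=j}^{N} |x_k - x_l| for k = 1..j-1 (1-based)
      for (int k = 1; k <= j - 1; ++k) {
        double acc = 0.0, xk = buf[k - 1];
        for (int l = j; l <= n; ++l) acc += std::fabs(xk - buf[l - 1]);
        a[k] = acc;
      }
      // num[i] = sum_{k=i}^{j-1} a[k]
      num[j - 1] = a[j - 1];
      for (int i = j - 2; i >= 1; --i) num[i] = num[i + 1] + a[i];
      for (int i = 1; i <= j - 1; ++i) {
        double c = num[i] / (double(j - i) * double(n - j + 1));
        if (c > best) best = c;
      }
    }
    out[s] = best;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector mbcd_series(NumericVector x, int window, double lambda) {
  const int t = x.size(), n = window;
  if (n < 3) stop("window must be >= 3");
  if (t < n) stop("series shorter than window");
  const int m = t - n + 1;
  const bool silverman = lambda <= 0;  // lambda <= 0 marks "per-buffer rule"
  NumericVector out(m);
  // w[l][k] kernel weights, 1-based; weight sums are accumulated directly
  // (never by differencing running sums) because underflowed weights make
  // cancellation errors dominate the log-ratios
  std::vector< std::vector<double> > w(n + 1, std::vector<double>(n + 1));
  std::vector<double> post_log(n + 1), pre_sum(n + 1);
  const double floor_w = 1e-300;
  for (int s = 0; s < m; ++s) {
    const double *buf = &x[s];
    double lam = lambda;
    if (silverman) {
      double mean = 0.0;
      for (int k = 0; k < n; ++k) mean += buf[k];
      mean /= n;
      double ss = 0.0;
      for (int k = 0; k < n; ++k) ss += (buf[k] - mean) * (buf[k] - mean);
      double sd = std::sqrt(ss / (n - 1));
      lam = 1.06 * sd * std::pow(double(n), -0.2);
      if (lam < 1e-6) lam = 1e-6;
    }
    const double inv2l2 = 0.5 / (lam * lam);
    for (int l = 1; l <= n; ++l)
      for (int k = 1; k <= n; ++k) {
        double d = buf[l - 1] - buf[k - 1];
        w[l][k] = std::exp(-d * d * inv2l2);
      }
    double best = R_NegInf;
    for (int j = 2; j <= n; ++j) {
      // post-change mean weight per band l (depends on j only)
      for (int l = j; l <= n; ++l) {
        double acc = 0.0;
        for (int k = j; k <= n; ++k) acc += w[l][k];
        double post = acc / double(n - j + 1);
        post_log[l] = std::log(post < floor_w ? floor_w : post);
        pre_sum[l] = 0.0;
      }
      // grow the first window downward from i = j-1 (additions only)
      for (int i = j - 1; i >= 1; --i) {
        double sij = 0.0;
        for (int l = j; l <= n; ++l) {
          pre_sum[l] += w[l][i];
          double pre = pre_sum[l] / double(j - i);
          sij += post_log[l] - std::log(pre < floor_w ? floor_w : pre);
        }
        if (sij > best) best = sij;
      }
    }
    out[s] = best;
  }
  return out;
}
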