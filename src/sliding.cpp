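#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Sliding-window statistics with stride 1. For an n x C signal matrix and
// window of W samples, returns an (n - W + 1) x (8 * C) matrix laid out
// channel-major with the per-channel statistic order
//   mean, std, var, max, min, range, kurtosis, skewness.
// Variance is the population (1/n) estimator; skewness and kurtosis are the
// uncorrected moment estimators (kurtosis on the normal-baseline-3
// convention). On a constant window std = var = range = 0 and kurtosis and
// skewness are defined as 0. Min/max use a monotonic deque; the central
// moments are computed two-pass per window (mean from a prefix sum, then
// centred powers) -- running power sums of x^3/x^4 lose too much precision
// to cancellation on high-magnitude channels.
// [[Rcpp::export]]
NumericMatrix sliding_stats_cpp(NumericMatrix x, int W) {
  const int n = x.nrow(), C = x.ncol();
  if (W < 1) stop("window size must be >= 1");
  if (n < W) stop("stream-too-short: %d samples < window of %d", n, W);
  const int m = n - W + 1;
  NumericMatrix out(m, 8 * C);
  const double dW = (double)W;

  for (int c = 0; c < C; ++c) {
    NumericMatrix::Column col = x(_, c);
    // sliding min and max via monotonic deques
    std::deque<int> qmin, qmax;
    std::vector<double> wmin(m), wmax(m);
    for (int i = 0; i < n; ++i) {
      while (!qmin.empty() && col[qmin.back()] >= col[i]) qmin.pop_back();
      qmin.push_back(i);
      while (!qmax.empty() && col[qmax.back()] <= col[i]) qmax.pop_back();
      qmax.push_back(i);
      if (i >= W - 1) {
        int j = i - W + 1;
        if (qmin.front() < j) qmin.pop_front();
        if (qmax.front() < j) qmax.pop_front();
        wmin[j] = col[qmin.front()];
        wmax[j] = col[qmax.front()];
      }
    }
    const int o = 8 * c;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int i = j; i < j + W; ++i) s += col[i];
      double mu = s / dW;
      double mx = wmax[j], mn = wmin[j];
      double sdv, var, rng, kur, skw;
      if (mx == mn) {
        sdv = var = rng = kur = skw = 0.0;
      } else {
        double m2 = 0.0, m3 = 0.0, m4 = 0.0;
        for (int i = j; i < j + W; ++i) {
          double dv = col[i] - mu, dv2 = dv * dv;
          m2 += dv2;
          m3 += dv2 * dv;
          m4 += dv2 * dv2;
        }
        m2 /= dW; m3 /= dW; m4 /= dW;
        var = m2;
        sdv = std::sqrt(m2);
        rng = mx - mn;
        if (m2 > 0) {
          skw = m3 / (m2 * sdv);
          kur = m4 / (m2 * m2);
        } else {
          skw = kur = 0.0;
        }
      }
      out(j, o + 0) = mu;
      out(j, o + 1) = sdv;
      out(j, o + 2) = var;
      out(j, o + 3) = mx;
      out(j, o + 4) = mn;
      out(j, o + 5) = rng;
      out(j, o + 6) = kur;
      out(j, o + 7) = skw;
    }
  }
  return out;
}
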