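#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// median identical to stats::median: middle order statistic, or the mean of
// the two middle order statistics for even length
static double median_inplace(std::vector<double> &v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lower = *std::max_element(v.begin(), v.begin() + h);
    m = (lower + m) / 2.0;
  }
  return m;
}

// Windowed median and robust noise level (MAD x 1.4826) of y over a
// centred window of half-width `halfwindow` samples at each (1-based)
// index in `idx`; windows are truncated at the array boundaries.
// Returns a matrix with columns (median, noise).
// [[Rcpp::export]]
NumericMatrix window_med_mad(NumericVector y, IntegerVector idx,
                             int halfwindow) {
  const int n = y.size();
  NumericMatrix out(idx.size(), 2);
  std::vector<double> buf, dev;
  for (int k = 0; k < idx.size(); ++k) {
    const int i = idx[k] - 1;
    const int lo = std::max(0, i - halfwindow);
    const int hi = std::min(n - 1, i + halfwindow);
    buf.assign(y.begin() + lo, y.begin() + hi + 1);
    const double med = median_inplace(buf);
    dev.resize(buf.size());
    for (size_t j = 0; j < buf.size(); ++j) {
      dev[j] = std::fabs(buf[j] - med);
    }
    out(k, 0) = med;
    out(k, 1) = 1.4826 * median_inplace(dev);
  }
  return out;
}
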