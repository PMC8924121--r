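#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Running trimmed mean over a centred window, truncated (not padded) at the
// signal edges. A sorted copy of the current window is maintained
// incrementally; per step one sample enters and one leaves, so the cost per
// output sample is O(W) rather than O(W log W).
//
// left/right: samples taken before/after the centre (window = left+1+right)
// trim_frac : fraction trimmed from EACH tail; count = floor(trim_frac * m)
//             where m is the actual (possibly truncated) window length.
// [[Rcpp::export(name = ".trimmed_running_mean_cpp")]]
NumericVector trimmed_running_mean_cpp(NumericVector x, int left, int right,
                                       double trim_frac) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;

  std::vector<double> win;
  win.reserve(left + right + 2);

  int lo = 0;                       // current window = [lo, hi]
  int hi = std::min(right, n - 1);  // window for centre index 0
  for (int j = lo; j <= hi; ++j) win.push_back(x[j]);
  std::sort(win.begin(), win.end());

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      int new_hi = std::min(i + right, n - 1);
      if (new_hi > hi) {
        double v = x[new_hi];
        win.insert(std::upper_bound(win.begin(), win.end(), v), v);
        hi = new_hi;
      }
      int new_lo = std::max(i - left, 0);
      if (new_lo > lo) {
        double v = x[lo];
        win.erase(std::lower_bound(win.begin(), win.end(), v));
        lo = new_lo;
      }
    }
    const int m = static_cast<int>(win.size());
    int k = static_cast<int>(std::floor(trim_frac * m));
    if (2 * k >= m) k = (m - 1) / 2;  // degenerate tiny windows: keep >=1 value
    double s = 0.0;
    for (int j = k; j < m - k; ++j) s += win[j];
    out[i] = s / (m - 2 * k);
  }
  return out;
}
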