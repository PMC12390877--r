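#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Mirror (symmetric, edge-repeating) index reflection: -1 -> 0, -2 -> 1,
// n -> n-1, n+1 -> n-2. Loops so that windows wider than the extent are
// still well defined, although callers reject those.
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Median of a scratch buffer; even counts average the two middle order
// statistics, matching stats::median().
static inline double buffer_median(std::vector<double>& buf) {
  const size_t k = buf.size();
  std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
  double hi = buf[k / 2];
  if (k % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
  return 0.5 * (lo + hi);
}

// Running median along the rows of a T x nvox matrix (one column per
// voxel time course), odd window, mirror padding.
// [[Rcpp::export(name = ".temporalMedianCpp")]]
NumericMatrix temporal_median_cpp(NumericMatrix x, int window) {
  const int T = x.nrow(), nv = x.ncol();
  const int off = (window - 1) / 2;
  NumericMatrix out(T, nv);
  std::vector<double> buf(window);
  for (int v = 0; v < nv; ++v) {
    for (int t = 0; t < T; ++t) {
      for (int j = 0; j < window; ++j)
        buf[j] = x(reflect_index(t - off + j, T), v);
      out(t, v) = buffer_median(buf);
    }
  }
  return out;
}

// In-plane median filter of a Y x X image with a ky x kx window whose
// origin sits at offset floor((k-1)/2) along each axis, mirror padding.
// [[Rcpp::export(name = ".spatialMedianCpp")]]
NumericMatrix spatial_median_cpp(NumericMatrix img, int ky, int kx) {
  const int Y = img.nrow(), X = img.ncol();
  const int offy = (ky - 1) / 2, offx = (kx - 1) / 2;
  NumericMatrix out(Y, X);
  std::vector<double> buf(ky * kx);
  for (int xx = 0; xx < X; ++xx) {
    for (int yy = 0; yy < Y; ++yy) {
      int b = 0;
      for (int i = 0; i < kx; ++i) {
        const int xi = reflect_index(xx - offx + i, X);
        for (int j = 0; j < ky; ++j)
          buf[b++] = img(reflect_index(yy - offy + j, Y), xi);
      }
      out(yy, xx) = buffer_median(buf);
    }
  }
  return out;
}
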