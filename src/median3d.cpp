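#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  // reflect index into [0, n): ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Sliding-window median over a cubic (2r+1)^3 window, edge-reflected.
// [[Rcpp::export]]
NumericVector cpp_median3d(const NumericVector& vol, int radius) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("volume must be a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericVector out((R_xlen_t)d1 * d2 * d3);
  out.attr("dim") = dims;
  const int w = 2 * radius + 1;
  std::vector<double> buf(w * w * w);
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        int m = 0;
        for (int c = -radius; c <= radius; ++c) {
          const R_xlen_t o3 = (R_xlen_t)d1 * d2 * reflect(i3 + c, d3);
          for (int b = -radius; b <= radius; ++b) {
            const R_xlen_t o2 = o3 + (R_xlen_t)d1 * reflect(i2 + b, d2);
            for (int a = -radius; a <= radius; ++a)
              buf[m++] = vol[o2 + reflect(i1 + a, d1)];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        double med = buf[m / 2];
        if (m % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m / 2);
          med = 0.5 * (med + buf[m / 2 - 1]);
        }
        out[i1 + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3)] = med;
      }
  return out;
}
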