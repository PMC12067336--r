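#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a 3D binary mask (dims nz, ny, nx in
// R array order: index = iz + nz*(iy + ny*ix) ... R arrays are column-major
// over dim = c(d1, d2, d3) so index = i1 + d1*(i2 + d2*i3).
// [[Rcpp::export]]
IntegerVector cpp_label26(const LogicalVector& mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++cur;
    lab[start] = cur;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      const int i1 = idx % d1;
      const int i2 = (idx / d1) % d2;
      const int i3 = idx / ((R_xlen_t)d1 * d2);
      for (int a = -1; a <= 1; ++a) {
        const int j1 = i1 + a;
        if (j1 < 0 || j1 >= d1) continue;
        for (int b = -1; b <= 1; ++b) {
          const int j2 = i2 + b;
          if (j2 < 0 || j2 >= d2) continue;
          for (int c = -1; c <= 1; ++c) {
            if (a == 0 && b == 0 && c == 0) continue;
            const int j3 = i3 + c;
            if (j3 < 0 || j3 >= d3) continue;
            const R_xlen_t j = j1 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
            if (mask[j] && lab[j] == 0) {
              lab[j] = cur;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  return lab;
}
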