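#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// bilinear sample with zero outside the grid; r, c are 0-based continuous indices
static inline double bilinear(const arma::mat& img, double r, double c) {
  const int nr = img.n_rows, nc = img.n_cols;
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) return 0.0;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < nr ? r0 + 1 : nr - 1;
  int c1 = c0 + 1 < nc ? c0 + 1 : nc - 1;
  double fr = r - r0, fc = c - c0;
  return (1.0 - fr) * ((1.0 - fc) * img(r0, c0) + fc * img(r0, c1)) +
         fr * ((1.0 - fc) * img(r1, c0) + fc * img(r1, c1));
}

// Discrete parallel-beam Radon transform of one slice.
// Projection at angle theta integrates along s with detector coordinate
// t = x cos(theta) + y sin(theta); unit step = one pixel; result scaled by
// pixel_mm so entries are line integrals in mu * mm.
// [[Rcpp::export]]
arma::mat cpp_radon(const arma::mat& img, const arma::vec& angles, double pixel_mm) {
  const int ndet = img.n_cols;
  const int na = angles.n_elem;
  const double cy = (img.n_rows - 1) / 2.0, cx = (img.n_cols - 1) / 2.0;
  const double cdet = (ndet - 1) / 2.0;
  const int nsteps = (int)std::ceil(std::sqrt((double)img.n_rows * img.n_rows +
                                              (double)img.n_cols * img.n_cols)) + 1;
  const double s0 = -(nsteps - 1) / 2.0;
  arma::mat sino(na, ndet, arma::fill::zeros);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int d = 0; d < ndet; ++d) {
      const double t = d - cdet;
      double acc = 0.0;
      for (int s = 0; s < nsteps; ++s) {
        const double ss = s0 + s;
        const double x = t * ct - ss * st;
        const double y = t * st + ss * ct;
        acc += bilinear(img, cy + y, cx + x);
      }
      sino(a, d) = acc * pixel_mm;
    }
  }
  return sino;
}

// Unfiltered backprojection of (already ramp-filtered) sinogram rows.
// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& fsino, const arma::vec& angles,
                          int ny, int nx) {
  const double cy = (ny - 1) / 2.0, cx = (nx - 1) / 2.0;
  const int ndet = fsino.n_cols;
  const double cdet = (ndet - 1) / 2.0;
  arma::mat img(ny, nx, arma::fill::zeros);
  for (arma::uword a = 0; a < angles.n_elem; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    const arma::rowvec row = fsino.row(a);
    for (int iy = 0; iy < ny; ++iy) {
      const double y = iy - cy;
      for (int ix = 0; ix < nx; ++ix) {
        const double x = ix - cx;
        const double t = x * ct + y * st + cdet;
        if (t < 0.0 || t > ndet - 1.0) continue;
        const int t0 = (int)t;
        const int t1 = t0 + 1 < ndet ? t0 + 1 : ndet - 1;
        const double ft = t - t0;
        img(iy, ix) += (1.0 - ft) * row[t0] + ft * row[t1];
      }
    }
  }
  return img;
}
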