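#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Mixed-scale dense convolutional network: every layer adds one channel,
// computed from ALL previous channels by dilated 3x3 convolutions (dilations
// cycling 1..maxDil) + bias + ReLU; the output is a 1x1 linear combination
// of all channels.  Training uses MSE and Adam.  A self-contained xorshift
// RNG makes init/shuffling bit-reproducible for a given seed.

struct RNG64 {
  uint64_t s;
  explicit RNG64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

struct MSDSpec {
  int C0, D, H, W;
  std::vector<int> dil;
  std::vector<size_t> layerOff;
  size_t outOff, nPar;
};

static MSDSpec makeSpec(int C0, int D, int H, int W, int maxDil) {
  MSDSpec s;
  s.C0 = C0; s.D = D; s.H = H; s.W = W;
  size_t off = 0;
  for (int i = 0; i < D; ++i) {
    s.dil.push_back(i % maxDil + 1);
    s.layerOff.push_back(off);
    off += 9 * (size_t)(C0 + i) + 1;
  }
  s.outOff = off;
  s.nPar = off + (size_t)(C0 + D) + 1;
  return s;
}

// out(r,c) += sum_k k[kk] * X(r+dy, c+dx), zero padded, same size
// (raw column-pointer loops: no temporaries, this is the training hot path)
static void conv_add(const arma::mat& X, const double* k, int d, arma::mat& out) {
  const int H = X.n_rows, W = X.n_cols;
  for (int kk = 0; kk < 9; ++kk) {
    const double w = k[kk];
    if (w == 0.0) continue;
    const int dy = (kk / 3 - 1) * d, dx = (kk % 3 - 1) * d;
    const int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
    const int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
    if (r0 > r1 || c0 > c1) continue;
    const int n = r1 - r0 + 1;
    for (int c = c0; c <= c1; ++c) {
      double* o = out.colptr(c) + r0;
      const double* x = X.colptr(c + dx) + r0 + dy;
      for (int r = 0; r < n; ++r) o[r] += w * x[r];
    }
  }
}

// gk[kk] += sum_{r,c} gz(r,c) * X(r+dy, c+dx)
static void conv_grad(const arma::mat& X, const arma::mat& gz, int d, double* gk) {
  const int H = X.n_rows, W = X.n_cols;
  for (int kk = 0; kk < 9; ++kk) {
    const int dy = (kk / 3 - 1) * d, dx = (kk % 3 - 1) * d;
    const int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
    const int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
    if (r0 > r1 || c0 > c1) continue;
    const int n = r1 - r0 + 1;
    double acc = 0.0;
    for (int c = c0; c <= c1; ++c) {
      const double* g = gz.colptr(c) + r0;
      const double* x = X.colptr(c + dx) + r0 + dy;
      for (int r = 0; r < n; ++r) acc += g[r] * x[r];
    }
    gk[kk] += acc;
  }
}

// gX(r+dy, c+dx) += k[kk] * gz(r,c)
static void conv_back(const arma::mat& gz, const double* k, int d, arma::mat& gX) {
  const int H = gz.n_rows, W = gz.n_cols;
  for (int kk = 0; kk < 9; ++kk) {
    const double w = k[kk];
    if (w == 0.0) continue;
    const int dy = (kk / 3 - 1) * d, dx = (kk % 3 - 1) * d;
    const int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
    const int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
    if (r0 > r1 || c0 > c1) continue;
    const int n = r1 - r0 + 1;
    for (int c = c0; c <= c1; ++c) {
      double* o = gX.colptr(c + dx) + r0 + dy;
      const double* g = gz.colptr(c) + r0;
      for (int r = 0; r < n; ++r) o[r] += w * g[r];
    }
  }
}

static void forwardSample(const arma::vec& P, const MSDSpec& sp,
                          const arma::cube& inputs, int pairIdx,
                          std::vector<arma::mat>& ch, arma::mat& out) {
  for (int j = 0; j < sp.C0; ++j) ch[j] = inputs.slice((size_t)pairIdx * sp.C0 + j);
  for (int i = 0; i < sp.D; ++i) {
    const double* blk = P.memptr() + sp.layerOff[i];
    const int nin = sp.C0 + i;
    arma::mat z(sp.H, sp.W);
    z.fill(blk[9 * nin]);
    for (int j = 0; j < nin; ++j) conv_add(ch[j], blk + 9 * j, sp.dil[i], z);
    z.for_each([](double& v) { if (v < 0.0) v = 0.0; });
    ch[sp.C0 + i] = std::move(z);
  }
  const double* ob = P.memptr() + sp.outOff;
  const int nch = sp.C0 + sp.D;
  out.set_size(sp.H, sp.W);
  out.fill(ob[nch]);
  for (int j = 0; j < nch; ++j) out += ob[j] * ch[j];
}

static double backwardSample(const arma::vec& P, const MSDSpec& sp,
                             const std::vector<arma::mat>& ch, const arma::mat& out,
                             const arma::mat& target, arma::vec& G,
                             std::vector<arma::mat>& gch) {
  const int nch = sp.C0 + sp.D;
  const double npix = (double)sp.H * sp.W;
  arma::mat diff = out - target;
  const double loss = arma::accu(diff % diff) / npix;
  arma::mat gout = (2.0 / npix) * diff;
  const double* ob = P.memptr() + sp.outOff;
  double* go = G.memptr() + sp.outOff;
  go[nch] += arma::accu(gout);
  for (int j = 0; j < nch; ++j) {
    go[j] += arma::accu(ch[j] % gout);
    gch[j].zeros(sp.H, sp.W);
    if (ob[j] != 0.0) gch[j] += ob[j] * gout;
  }
  for (int i = sp.D - 1; i >= 0; --i) {
    const int c = sp.C0 + i, nin = sp.C0 + i;
    arma::mat gz = gch[c];
    gz.elem(arma::find(ch[c] <= 0.0)).zeros();
    const double* blk = P.memptr() + sp.layerOff[i];
    double* gblk = G.memptr() + sp.layerOff[i];
    gblk[9 * nin] += arma::accu(gz);
    for (int j = 0; j < nin; ++j) {
      conv_grad(ch[j], gz, sp.dil[i], gblk + 9 * j);
      conv_back(gz, blk + 9 * j, sp.dil[i], gch[j]);
    }
  }
  return loss;
}

static double evalLoss(const arma::vec& P, const MSDSpec& sp,
                       const arma::cube& inputs, const arma::cube& targets,
                       const IntegerVector& idx,
                       std::vector<arma::mat>& ch, arma::mat& out) {
  if (idx.size() == 0) return NA_REAL;
  double tot = 0.0;
  const double npix = (double)sp.H * sp.W;
  for (int q = 0; q < idx.size(); ++q) {
    forwardSample(P, sp, inputs, idx[q], ch, out);
    arma::mat diff = out - targets.slice(idx[q]);
    tot += arma::accu(diff % diff) / npix;
  }
  return tot / idx.size();
}

// [[Rcpp::export]]
List cpp_msd_train(const arma::cube& inputs, const arma::cube& targets,
                   int slab, int depth, const IntegerVector& trainIdx,
                   const IntegerVector& valIdx, double lr, int batch,
                   int epochs, double seed, int maxDil) {
  const int H = targets.n_rows, W = targets.n_cols;
  if (inputs.n_slices != (size_t)targets.n_slices * slab)
    stop("inputs/targets size mismatch");
  MSDSpec sp = makeSpec(slab, depth, H, W, maxDil);
  RNG64 rng((uint64_t)(seed) * 2654435761ULL + 1442695040888963407ULL);

  arma::vec P(sp.nPar, arma::fill::zeros);
  for (int i = 0; i < depth; ++i) {
    const int nin = slab + i;
    const double sd = std::sqrt(2.0 / (9.0 * nin));
    double* blk = P.memptr() + sp.layerOff[i];
    for (int j = 0; j < 9 * nin; ++j) blk[j] = sd * rng.norm();
    blk[9 * nin] = 0.0;
  }
  // output layer starts at zero: first prediction is the (normalized) mean

  arma::vec M(sp.nPar, arma::fill::zeros), V(sp.nPar, arma::fill::zeros);
  arma::vec G(sp.nPar);
  std::vector<arma::mat> ch(slab + depth), gch(slab + depth);
  arma::mat out;
  std::vector<int> tr(trainIdx.begin(), trainIdx.end());
  const bool hasVal = valIdx.size() > 0;

  arma::mat logmat(epochs + 1, 2);
  logmat(0, 0) = evalLoss(P, sp, inputs, targets, trainIdx, ch, out);
  logmat(0, 1) = hasVal ? evalLoss(P, sp, inputs, targets, valIdx, ch, out)
                        : logmat(0, 0);
  arma::vec bestP = P;
  double bestVal = logmat(0, 1);
  int bestEpoch = 0;
  long step = 0;

  for (int e = 0; e < epochs; ++e) {
    for (int i = (int)tr.size() - 1; i > 0; --i) {
      int j = (int)(rng.unif() * (i + 1));
      if (j > i) j = i;
      std::swap(tr[i], tr[j]);
    }
    for (size_t b0 = 0; b0 < tr.size(); b0 += batch) {
      const size_t b1 = std::min(b0 + (size_t)batch, tr.size());
      G.zeros();
      for (size_t q = b0; q < b1; ++q) {
        forwardSample(P, sp, inputs, tr[q], ch, out);
        backwardSample(P, sp, ch, out, targets.slice(tr[q]), G, gch);
      }
      G /= (double)(b1 - b0);
      ++step;
      M = 0.9 * M + 0.1 * G;
      V = 0.999 * V + 0.001 * (G % G);
      const double c1 = 1.0 - std::pow(0.9, (double)step);
      const double c2 = 1.0 - std::pow(0.999, (double)step);
      P -= lr * (M / c1) / (arma::sqrt(V / c2) + 1e-8);
    }
    const double trLoss = evalLoss(P, sp, inputs, targets, trainIdx, ch, out);
    const double vaLoss = hasVal ? evalLoss(P, sp, inputs, targets, valIdx, ch, out)
                                 : trLoss;
    if (!std::isfinite(trLoss) || !std::isfinite(vaLoss))
      stop("non-finite loss at epoch %d (train=%g, val=%g); lower the learning rate",
           e + 1, trLoss, vaLoss);
    logmat(e + 1, 0) = trLoss;
    logmat(e + 1, 1) = vaLoss;
    if (vaLoss < bestVal) {
      bestVal = vaLoss;
      bestP = P;
      bestEpoch = e + 1;
    }
  }
  return List::create(_["params"] = bestP, _["finalParams"] = P,
                      _["log"] = logmat, _["bestEpoch"] = bestEpoch);
}

// [[Rcpp::export]]
arma::cube cpp_msd_predict(const arma::vec& params, const arma::cube& inputs,
                           int slab, int depth, int maxDil) {
  const int H = inputs.n_rows, W = inputs.n_cols;
  if (inputs.n_slices % slab != 0) stop("input slice count not a multiple of slab");
  const int n = inputs.n_slices / slab;
  MSDSpec sp = makeSpec(slab, depth, H, W, maxDil);
  if (params.n_elem != sp.nPar)
    stop("parameter vector length mismatch (got %d, need %d)",
         (int)params.n_elem, (int)sp.nPar);
  arma::cube out(H, W, n);
  std::vector<arma::mat> ch(slab + depth);
  arma::mat o;
  for (int p = 0; p < n; ++p) {
    forwardSample(params, sp, inputs, p, ch, o);
    out.slice(p) = o;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_msd_n_params(int slab, int depth, int maxDil) {
  return (double)makeSpec(slab, depth, 8, 8, maxDil).nPar;
}
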