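// 3-D convolutional VAE engine: im2col/GEMM convolutions, analytic backprop,
// Adam updates. All randomness (init, reparameterization noise, shuffling)
// is drawn in R and passed in, so results are reproducible from one R seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Geometry of the fixed stack: two stride-2 k=3 p=1 conv layers D -> D/2 -> D/4,
// mirrored by two transposed convs in the decoder. D must be divisible by 4.
struct Dims {
  int D, S, d, f1, f2;
  int V, N1, N2, F;
  Dims(int D_, int S_, int d_, int f1_, int f2_) :
    D(D_), S(S_), d(d_), f1(f1_), f2(f2_) {
    V = D * D * D;
    int D1 = D / 2, D2 = D / 4;
    N1 = D1 * D1 * D1;
    N2 = D2 * D2 * D2;
    F = f2 * N2;
  }
};

// Gather map for k=3, s=2, p=1 convolution on a cube of side Din.
// gmap(off, n) = source voxel index in the input cube, or -1 (zero pad).
static imat conv_gather(int Din) {
  int Dout = Din / 2;
  int Nout = Dout * Dout * Dout;
  imat g(27, Nout);
  for (int oz = 0; oz < Dout; ++oz)
    for (int oy = 0; oy < Dout; ++oy)
      for (int ox = 0; ox < Dout; ++ox) {
        int n = ox + Dout * (oy + Dout * oz);
        for (int kz = 0; kz < 3; ++kz)
          for (int ky = 0; ky < 3; ++ky)
            for (int kx = 0; kx < 3; ++kx) {
              int off = kx + 3 * (ky + 3 * kz);
              int ix = 2 * ox - 1 + kx, iy = 2 * oy - 1 + ky, iz = 2 * oz - 1 + kz;
              g(off, n) = (ix >= 0 && ix < Din && iy >= 0 && iy < Din &&
                           iz >= 0 && iz < Din)
                ? ix + Din * (iy + Din * iz) : -1;
            }
      }
  return g;
}

// X: (C x Nin*B) feature maps, column-contiguous per voxel; returns
// col matrix (27*C x Nout*B), row block off*C + c.
static mat vol2col(const mat& X, const imat& g, int C, int Nin, int B) {
  int Nout = g.n_cols;
  mat col(27 * C, (size_t)Nout * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr((size_t)b * Nin);
    for (int n = 0; n < Nout; ++n) {
      double* cb = col.colptr((size_t)b * Nout + n);
      for (int off = 0; off < 27; ++off) {
        long src = g(off, n);
        if (src >= 0) std::memcpy(cb + off * C, xb + src * C, C * sizeof(double));
      }
    }
  }
  return col;
}

// Adjoint of vol2col: scatter-add col (27*C x Nout*B) back to (C x Nin*B).
static mat col2vol(const mat& col, const imat& g, int C, int Nin, int B) {
  int Nout = g.n_cols;
  mat X(C, (size_t)Nin * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* xb = X.colptr((size_t)b * Nin);
    for (int n = 0; n < Nout; ++n) {
      const double* cb = col.colptr((size_t)b * Nout + n);
      for (int off = 0; off < 27; ++off) {
        long src = g(off, n);
        if (src >= 0) {
          double* dst = xb + src * C;
          const double* s = cb + off * C;
          for (int c = 0; c < C; ++c) dst[c] += s[c];
        }
      }
    }
  }
  return X;
}

// Weight order per model, used everywhere (R keeps the same list order):
// for each space s: W1 (f1 x 27), b1, W2 (f2 x 27*f1), b2,
//                   Wmu (d x F), bmu, Wlv (d x F), blv
// decoder: Wd (F x S*d), bd, V1 (f2 x 27*f1), c1 (f1), V2 (f1 x 27), c2 (1)
static std::vector<mat> unpack(const Rcpp::List& w) {
  std::vector<mat> out;
  for (int i = 0; i < w.size(); ++i) out.push_back(Rcpp::as<mat>(w[i]));
  return out;
}
static Rcpp::List pack(const std::vector<mat>& w, const Rcpp::List& proto) {
  Rcpp::List out(w.size());
  out.names() = proto.names();
  for (size_t i = 0; i < w.size(); ++i) out[i] = w[i];
  return out;
}

struct Cache {            // per-batch forward intermediates
  mat col1, A1, col2, A2; // per space, overwritten sequentially -> store per space
};

// Forward pass of one encoder space; returns H (F x B), keeps intermediates.
static void enc_forward(const std::vector<mat>& w, int s, const mat& Xb,
                        const Dims& dm, const imat& g0, const imat& g1,
                        int B, mat& col1, mat& A1, mat& col2, mat& A2, mat& H) {
  const mat &W1 = w[8 * s], &b1 = w[8 * s + 1], &W2 = w[8 * s + 2], &b2 = w[8 * s + 3];
  col1 = vol2col(Xb, g0, 1, dm.V, B);
  A1 = W1 * col1;
  A1.each_col() += b1.col(0);
  A1.transform([](double v) { return v > 0 ? v : 0.0; });
  col2 = vol2col(A1, g1, dm.f1, dm.N1, B);
  A2 = W2 * col2;
  A2.each_col() += b2.col(0);
  A2.transform([](double v) { return v > 0 ? v : 0.0; });
  H.set_size(dm.F, B);                       // flatten: memory layout matches
  std::memcpy(H.memptr(), A2.memptr(), sizeof(double) * dm.F * B);
}

// Decoder forward from masked latent Z (S*d x B); returns Xhat (V x B).
static void dec_forward(const std::vector<mat>& w, const mat& Z, const Dims& dm,
                        const imat& g0, const imat& g1, int B,
                        mat& Hd, mat& G, mat& U, mat& Xhat) {
  int o = 8 * dm.S;
  const mat &Wd = w[o], &bd = w[o + 1], &V1 = w[o + 2], &c1 = w[o + 3],
            &V2 = w[o + 4], &c2 = w[o + 5];
  Hd = Wd * Z;
  Hd.each_col() += bd.col(0);
  Hd.transform([](double v) { return v > 0 ? v : 0.0; });
  G.set_size(dm.f2, (size_t)dm.N2 * B);
  std::memcpy(G.memptr(), Hd.memptr(), sizeof(double) * dm.F * B);
  mat colu = V1.t() * G;                     // (27*f1 x N2*B)
  U = col2vol(colu, g1, dm.f1, dm.N1, B);    // (f1 x N1*B), channel per row
  U.each_col() += c1.col(0);
  U.transform([](double v) { return v > 0 ? v : 0.0; });
  mat colx = V2.t() * U;                     // (27 x N1*B)
  Xhat = col2vol(colx, g0, 1, dm.V, B);
  Xhat += c2(0, 0);
  Xhat.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  Xhat.reshape(dm.V, B);
}

// Full forward+backward on one batch. Returns grads in `gr` (same order as w),
// and mse/kl sums (per-subject sums, caller averages).
static void batch_grad(const std::vector<mat>& w, const mat& Xb, const mat& maskb,
                       const mat& klmaskb, const std::vector<mat>& epsb,
                       const Dims& dm, const imat& g0, const imat& g1,
                       double klw, std::vector<mat>& gr,
                       double& mse_sum, double& kl_sum) {
  int B = Xb.n_cols;
  int S = dm.S, d = dm.d;
  std::vector<mat> col1(S), A1(S), col2(S), A2(S), H(S), mu(S), lv(S), z(S);
  mat Xin = Xb;
  Xin.reshape(1, (size_t)dm.V * B);
  for (int s = 0; s < S; ++s) {
    enc_forward(w, s, Xin, dm, g0, g1, B, col1[s], A1[s], col2[s], A2[s], H[s]);
    const mat &Wmu = w[8 * s + 4], &bmu = w[8 * s + 5],
              &Wlv = w[8 * s + 6], &blv = w[8 * s + 7];
    mu[s] = Wmu * H[s]; mu[s].each_col() += bmu.col(0);
    lv[s] = Wlv * H[s]; lv[s].each_col() += blv.col(0);
    z[s] = mu[s] + exp(0.5 * lv[s]) % epsb[s];
    z[s].each_row() %= maskb.row(s);         // zero substitution for inactive
  }
  mat Z(S * d, B);
  for (int s = 0; s < S; ++s) Z.rows(s * d, (s + 1) * d - 1) = z[s];
  mat Hd, G, U, Xhat;
  dec_forward(w, Z, dm, g0, g1, B, Hd, G, U, Xhat);

  mat R = Xhat - Xb;
  mse_sum = accu(R % R);
  kl_sum = 0.0;
  for (int s = 0; s < S; ++s) {
    mat k = 0.5 * (square(mu[s]) + exp(lv[s]) - 1.0 - lv[s]);
    kl_sum += accu(sum(k, 0) % klmaskb.row(s));
  }

  // ----- backward -----
  int o = 8 * S;
  const mat &Wd = w[o], &V1 = w[o + 2], &V2 = w[o + 4];
  double invB = 1.0 / B;
  mat dlog = (2.0 * invB) * (R % Xhat % (1.0 - Xhat)); // (V x B)
  dlog.reshape(1, (size_t)dm.V * B);
  mat dcolx = vol2col(dlog, g0, 1, dm.V, B);           // (27 x N1*B)
  gr[o + 4] = U * dcolx.t();                           // dV2 (f1 x 27)
  gr[o + 5] = mat(1, 1, fill::value(accu(dlog)));      // dc2
  mat dU = V2 * dcolx;                                 // (f1 x N1*B)
  dU %= conv_to<mat>::from(U > 0);
  gr[o + 3] = sum(dU, 1);                              // dc1 (f1 x 1)
  mat dcolu = vol2col(dU, g1, dm.f1, dm.N1, B);        // (27*f1 x N2*B)
  gr[o + 2] = G * dcolu.t();                           // dV1 (f2 x 27*f1)
  mat dG = V1 * dcolu;                                 // (f2 x N2*B)
  mat dHd(dm.F, B);
  std::memcpy(dHd.memptr(), dG.memptr(), sizeof(double) * dm.F * B);
  dHd %= conv_to<mat>::from(Hd > 0);
  gr[o] = dHd * Z.t();                                 // dWd
  gr[o + 1] = sum(dHd, 1);                             // dbd
  mat dZ = Wd.t() * dHd;                               // (S*d x B)

  for (int s = 0; s < S; ++s) {
    mat dz = dZ.rows(s * d, (s + 1) * d - 1);
    dz.each_row() %= maskb.row(s);                     // gradient gated too
    mat dmu = dz;
    mat dlv = 0.5 * dz % exp(0.5 * lv[s]) % epsb[s];
    // KL gradients for the penalized subjects, averaged over batch
    mat am = repmat(klmaskb.row(s), d, 1);
    dmu += (klw * invB) * (mu[s] % am);
    dlv += (0.5 * klw * invB) * ((exp(lv[s]) - 1.0) % am);
    const mat &Wmu = w[8 * s + 4], &Wlv = w[8 * s + 6], &W2 = w[8 * s + 2];
    gr[8 * s + 4] = dmu * H[s].t();
    gr[8 * s + 5] = sum(dmu, 1);
    gr[8 * s + 6] = dlv * H[s].t();
    gr[8 * s + 7] = sum(dlv, 1);
    mat dH = Wmu.t() * dmu + Wlv.t() * dlv;            // (F x B)
    mat dA2(dm.f2, (size_t)dm.N2 * B);
    std::memcpy(dA2.memptr(), dH.memptr(), sizeof(double) * dm.F * B);
    dA2 %= conv_to<mat>::from(A2[s] > 0);
    gr[8 * s + 2] = dA2 * col2[s].t();
    gr[8 * s + 3] = sum(dA2, 1);
    mat dcol2 = W2.t() * dA2;
    mat dA1 = col2vol(dcol2, g1, dm.f1, dm.N1, B);
    dA1 %= conv_to<mat>::from(A1[s] > 0);
    gr[8 * s] = dA1 * col1[s].t();
    gr[8 * s + 1] = sum(dA1, 1);
  }
}

static Dims get_dims(const Rcpp::List& dims) {
  return Dims(Rcpp::as<int>(dims["D"]), Rcpp::as<int>(dims["S"]),
              Rcpp::as<int>(dims["d"]), Rcpp::as<int>(dims["f1"]),
              Rcpp::as<int>(dims["f2"]));
}

// One epoch of minibatch Adam. order: 0-based permutation of subjects.
// eps: list of (d x n) noise per space. mask: (S x n) activity indicators.
// [[Rcpp::export]]
Rcpp::List nn_train_epoch(Rcpp::List weights, Rcpp::List adam_m, Rcpp::List adam_v,
                          int step, const arma::mat& X, const arma::mat& mask,
                          const arma::mat& kl_mask, Rcpp::List eps,
                          const arma::ivec& order, Rcpp::List dims,
                          double lr, double klw, int batch) {
  Dims dm = get_dims(dims);
  std::vector<mat> w = unpack(weights), m = unpack(adam_m), v = unpack(adam_v);
  std::vector<mat> epsAll;
  for (int s = 0; s < dm.S; ++s) epsAll.push_back(Rcpp::as<mat>(eps[s]));
  imat g0 = conv_gather(dm.D), g1 = conv_gather(dm.D / 2);
  int n = order.n_elem;
  double mse_tot = 0, kl_tot = 0;
  const double b1 = 0.9, b2 = 0.999, epsA = 1e-8;
  std::vector<mat> gr(w.size());
  for (int start = 0; start < n; start += batch) {
    int B = std::min(batch, n - start);
    uvec idx(B);
    for (int i = 0; i < B; ++i) idx(i) = (uword)order(start + i);
    mat Xb = X.cols(idx);
    mat maskb = mask.cols(idx);
    mat klmaskb = kl_mask.cols(idx);
    std::vector<mat> epsb(dm.S);
    for (int s = 0; s < dm.S; ++s) epsb[s] = epsAll[s].cols(idx);
    double mse_s, kl_s;
    batch_grad(w, Xb, maskb, klmaskb, epsb, dm, g0, g1, klw, gr, mse_s, kl_s);
    mse_tot += mse_s; kl_tot += kl_s;
    ++step;
    double bc1 = 1.0 - std::pow(b1, step), bc2 = 1.0 - std::pow(b2, step);
    for (size_t i = 0; i < w.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * gr[i];
      v[i] = b2 * v[i] + (1 - b2) * square(gr[i]);
      w[i] -= lr * (m[i] / bc1) / (sqrt(v[i] / bc2) + epsA);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = pack(w, weights),
    Rcpp::Named("m") = pack(m, adam_m), Rcpp::Named("v") = pack(v, adam_v),
    Rcpp::Named("step") = step,
    Rcpp::Named("mse") = mse_tot / n, Rcpp::Named("kl") = kl_tot / n);
}

// Gradient of the batch loss at given weights (for finite-difference checks).
// [[Rcpp::export]]
Rcpp::List nn_grad(Rcpp::List weights, const arma::mat& X, const arma::mat& mask,
                   const arma::mat& kl_mask, Rcpp::List eps, Rcpp::List dims,
                   double klw) {
  Dims dm = get_dims(dims);
  std::vector<mat> w = unpack(weights);
  std::vector<mat> epsb;
  for (int s = 0; s < dm.S; ++s) epsb.push_back(Rcpp::as<mat>(eps[s]));
  imat g0 = conv_gather(dm.D), g1 = conv_gather(dm.D / 2);
  std::vector<mat> gr(w.size());
  double mse_s, kl_s;
  batch_grad(w, X, mask, kl_mask, epsb, dm, g0, g1, klw, gr, mse_s, kl_s);
  int B = X.n_cols;
  return Rcpp::List::create(
    Rcpp::Named("grads") = pack(gr, weights),
    Rcpp::Named("mse") = mse_s / B, Rcpp::Named("kl") = kl_s / B);
}

// Posterior means and log-variances for all subjects. Deterministic.
// [[Rcpp::export]]
Rcpp::List nn_encode(Rcpp::List weights, const arma::mat& X, Rcpp::List dims) {
  Dims dm = get_dims(dims);
  std::vector<mat> w = unpack(weights);
  imat g0 = conv_gather(dm.D), g1 = conv_gather(dm.D / 2);
  int n = X.n_cols, chunk = 64;
  std::vector<mat> mus(dm.S), lvs(dm.S);
  for (int s = 0; s < dm.S; ++s) { mus[s].set_size(dm.d, n); lvs[s].set_size(dm.d, n); }
  for (int start = 0; start < n; start += chunk) {
    int B = std::min(chunk, n - start);
    mat Xb = X.cols(start, start + B - 1);
    Xb.reshape(1, (size_t)dm.V * B);
    for (int s = 0; s < dm.S; ++s) {
      mat col1, A1, col2, A2, H;
      enc_forward(w, s, Xb, dm, g0, g1, B, col1, A1, col2, A2, H);
      mat mu = w[8 * s + 4] * H; mu.each_col() += w[8 * s + 5].col(0);
      mat lvv = w[8 * s + 6] * H; lvv.each_col() += w[8 * s + 7].col(0);
      mus[s].cols(start, start + B - 1) = mu;
      lvs[s].cols(start, start + B - 1) = lvv;
    }
  }
  Rcpp::List muL(dm.S), lvL(dm.S);
  for (int s = 0; s < dm.S; ++s) { muL[s] = mus[s]; lvL[s] = lvs[s]; }
  return Rcpp::List::create(Rcpp::Named("mu") = muL, Rcpp::Named("logvar") = lvL);
}

// Decode from latent matrix Z (S*d x n); caller applies any zeroing.
// [[Rcpp::export]]
arma::mat nn_decode(Rcpp::List weights, const arma::mat& Z, Rcpp::List dims) {
  Dims dm = get_dims(dims);
  std::vector<mat> w = unpack(weights);
  imat g0 = conv_gather(dm.D), g1 = conv_gather(dm.D / 2);
  int n = Z.n_cols, chunk = 64;
  mat out(dm.V, n);
  for (int start = 0; start < n; start += chunk) {
    int B = std::min(chunk, n - start);
    mat Hd, G, U, Xhat;
    dec_forward(w, Z.cols(start, start + B - 1), dm, g0, g1, B, Hd, G, U, Xhat);
    out.cols(start, start + B - 1) = Xhat;
  }
  return out;
}

// Pull-back warp with trilinear interpolation and zero fill outside the grid.
// vol: (V), disp: (V x 3) displacement in voxels, dims c(dx,dy,dz).
// [[Rcpp::export]]
arma::vec warp_pullback(const arma::vec& vol, const arma::mat& disp,
                        const arma::ivec& dim) {
  int dx = dim(0), dy = dim(1), dz = dim(2);
  vec out(vol.n_elem, fill::zeros);
  auto at = [&](int x, int y, int z) -> double {
    if (x < 0 || x >= dx || y < 0 || y >= dy || z < 0 || z >= dz) return 0.0;
    return vol[(size_t)x + dx * ((size_t)y + dy * (size_t)z)];
  };
  size_t v = 0;
  for (int z = 0; z < dz; ++z)
    for (int y = 0; y < dy; ++y)
      for (int x = 0; x < dx; ++x, ++v) {
        double sx = x - disp(v, 0), sy = y - disp(v, 1), sz = z - disp(v, 2);
        double fx = std::floor(sx), fy = std::floor(sy), fz = std::floor(sz);
        double tx = sx - fx, ty = sy - fy, tz = sz - fz;
        int ix = (int)fx, iy = (int)fy, iz = (int)fz;
        double c00 = at(ix, iy, iz) * (1 - tx) + at(ix + 1, iy, iz) * tx;
        double c10 = at(ix, iy + 1, iz) * (1 - tx) + at(ix + 1, iy + 1, iz) * tx;
        double c01 = at(ix, iy, iz + 1) * (1 - tx) + at(ix + 1, iy, iz + 1) * tx;
        double c11 = at(ix, iy + 1, iz + 1) * (1 - tx) + at(ix + 1, iy + 1, iz + 1) * tx;
        double c0 = c00 * (1 - ty) + c10 * ty;
        double c1 = c01 * (1 - ty) + c11 * ty;
        out[v] = c0 * (1 - tz) + c1 * tz;
      }
  return out;
}

// ---- Kendall tau-b by Knight's O(m log m) algorithm ----
static double merge_count(std::vector<double>& a, std::vector<double>& buf,
                          size_t lo, size_t hi) {
  if (hi - lo < 2) return 0.0;
  size_t mid = (lo + hi) / 2;
  double inv = merge_count(a, buf, lo, mid) + merge_count(a, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (a[j] < a[i]) { inv += mid - i; buf[k++] = a[j++]; }
    else buf[k++] = a[i++];
  }
  while (i < mid) buf[k++] = a[i++];
  while (j < hi) buf[k++] = a[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, a.begin() + lo);
  return inv;
}

// [[Rcpp::export]]
double kendall_tau_b(const arma::vec& x, const arma::vec& y) {
  size_t m = x.n_elem;
  if (m < 2) Rcpp::stop("need at least two observations");
  std::vector<size_t> ord(m);
  for (size_t i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return x[a] < x[b] || (x[a] == x[b] && y[a] < y[b]);
  });
  // tie counts in x (n1), joint ties (n3)
  double n1 = 0, n3 = 0;
  size_t i = 0;
  while (i < m) {
    size_t j = i;
    while (j < m && x[ord[j]] == x[ord[i]]) ++j;
    double t = j - i;
    n1 += t * (t - 1) / 2;
    size_t a = i;
    while (a < j) {
      size_t b = a;
      while (b < j && y[ord[b]] == y[ord[a]]) ++b;
      double u = b - a;
      n3 += u * (u - 1) / 2;
      a = b;
    }
    i = j;
  }
  std::vector<double> ys(m), buf(m);
  for (size_t k = 0; k < m; ++k) ys[k] = y[ord[k]];
  double swaps = merge_count(ys, buf, 0, m);
  // tie counts in y (n2)
  std::vector<double> ysort(ys);
  double n2 = 0;
  i = 0;
  while (i < m) {
    size_t j = i;
    while (j < m && ysort[j] == ysort[i]) ++j;
    double t = j - i;
    n2 += t * (t - 1) / 2;
    i = j;
  }
  double n0 = (double)m * (m - 1) / 2.0;
  double denom = std::sqrt((n0 - n1) * (n0 - n2));
  if (denom == 0) return NA_REAL;
  double num = n0 - n1 - n2 + n3 - 2.0 * swaps;
  return num / denom;
}
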