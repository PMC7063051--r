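// 3D convolution kernels for the cascaded segmentation network.
//
// Volumes are R arrays dim (nx, ny, nz, channels), x fastest, so a
// volume flattens to an (nvox x channels) column-major matrix. A k^3
// (optionally dilated) "same"-padded convolution is computed as a sum
// over kernel taps of shifted-volume GEMMs: Y += shift(X, off_t) * W_t,
// which routes all the arithmetic through BLAS sgemm. The backward pass
// reuses the same shift machinery for both the input gradient
// (scatter-add of DY * W_t^T) and the weight gradient (shift(X)^T * DY).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;

// dst[v] = src[v + off] with zero fill outside the grid; zeroes are
// written inline (only where needed) to keep memory traffic low
static void gather_shift(const fmat &X, fmat &Xs, int nx, int ny, int nz,
                         int ox, int oy, int oz) {
  const int C = (int)X.n_cols;
  const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
  const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
  const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
  if (x1 <= x0 || y1 <= y0 || z1 <= z0) { Xs.zeros(); return; }
  const size_t len = (size_t)(x1 - x0);
  const size_t plane = (size_t)nx * ny;
  for (int c = 0; c < C; ++c) {
    const float *src = X.colptr(c);
    float *dst = Xs.colptr(c);
    if (z0 > 0) std::memset(dst, 0, sizeof(float) * plane * z0);
    if (z1 < nz) std::memset(dst + plane * z1, 0,
                             sizeof(float) * plane * (nz - z1));
    for (int z = z0; z < z1; ++z) {
      const size_t zs = (size_t)(z + oz) * ny;
      float *dplane = dst + plane * z;
      if (y0 > 0) std::memset(dplane, 0, sizeof(float) * (size_t)nx * y0);
      if (y1 < ny) std::memset(dplane + (size_t)nx * y1, 0,
                               sizeof(float) * (size_t)nx * (ny - y1));
      for (int y = y0; y < y1; ++y) {
        float *drow = dplane + (size_t)nx * y;
        if (x0 > 0) std::memset(drow, 0, sizeof(float) * x0);
        if (x1 < nx) std::memset(drow + x1, 0, sizeof(float) * (nx - x1));
        std::memcpy(drow + x0,
                    src + x0 + ox + (size_t)nx * (y + oy + zs),
                    sizeof(float) * len);
      }
    }
  }
}

// dst[v + off] += src[v]
static void scatter_add_shift(const fmat &T, fmat &dX, int nx, int ny, int nz,
                              int ox, int oy, int oz) {
  const int C = (int)T.n_cols;
  const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
  const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
  const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
  if (x1 <= x0 || y1 <= y0 || z1 <= z0) return;
  const int len = x1 - x0;
  for (int c = 0; c < C; ++c) {
    const float *src = T.colptr(c);
    float *dst = dX.colptr(c);
    for (int z = z0; z < z1; ++z) {
      const size_t zs = (size_t)z * ny;
      const size_t zd = (size_t)(z + oz) * ny;
      for (int y = y0; y < y1; ++y) {
        float *d = dst + x0 + ox + (size_t)nx * (y + oy + zd);
        const float *s = src + x0 + (size_t)nx * (y + zs);
        for (int i = 0; i < len; ++i) d[i] += s[i];
      }
    }
  }
}

static int tap_center(int k) { return (k % 2 == 1) ? (k - 1) / 2 : k / 2 - 1; }

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector dims,
                         NumericMatrix w, NumericVector bias,
                         int k, int dil) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const size_t nvox = (size_t)nx * ny * nz;
  const int K = k * k * k;
  const int cout = w.ncol();
  if ((size_t)x.size() != nvox * cin) stop("input size mismatch");
  if (w.nrow() != K * cin) stop("weight shape mismatch");

  fmat X(nvox, cin);
  {
    const double *xp = x.begin();
    float *d = X.memptr();
    for (size_t i = 0; i < nvox * (size_t)cin; ++i) d[i] = (float)xp[i];
  }
  fmat Y(nvox, cout, arma::fill::zeros);
  fmat Xs(nvox, cin);
  fmat Wt(cin, cout);
  const int c0 = tap_center(k);
  for (int t = 0; t < K; ++t) {
    const int ox = dil * (t % k - c0);
    const int oy = dil * ((t / k) % k - c0);
    const int oz = dil * (t / (k * k) - c0);
    for (int ci = 0; ci < cin; ++ci)
      for (int co = 0; co < cout; ++co)
        Wt(ci, co) = (float)w(t + K * ci, co);
    gather_shift(X, Xs, nx, ny, nz, ox, oy, oz);
    Y += Xs * Wt;
  }
  for (int co = 0; co < cout; ++co) Y.col(co) += (float)bias[co];

  NumericVector out(nvox * (size_t)cout);
  {
    const float *s = Y.memptr();
    double *d = out.begin();
    for (size_t i = 0; i < nvox * (size_t)cout; ++i) d[i] = s[i];
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, IntegerVector dims, NumericVector dy,
                NumericMatrix w, int k, int dil, bool need_dx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const size_t nvox = (size_t)nx * ny * nz;
  const int K = k * k * k;
  const int cout = w.ncol();
  if ((size_t)x.size() != nvox * cin) stop("input size mismatch");
  if ((size_t)dy.size() != nvox * (size_t)cout) stop("grad size mismatch");

  fmat X(nvox, cin), DY(nvox, cout);
  {
    const double *p = x.begin();
    float *d = X.memptr();
    for (size_t i = 0; i < nvox * (size_t)cin; ++i) d[i] = (float)p[i];
    p = dy.begin();
    d = DY.memptr();
    for (size_t i = 0; i < nvox * (size_t)cout; ++i) d[i] = (float)p[i];
  }

  fmat dX;
  if (need_dx) dX.zeros(nvox, cin);
  NumericMatrix dw(K * cin, cout);
  fmat Xs(nvox, cin), Wt(cin, cout), dWt(cin, cout), T(nvox, cin);
  const int c0 = tap_center(k);
  for (int t = 0; t < K; ++t) {
    const int ox = dil * (t % k - c0);
    const int oy = dil * ((t / k) % k - c0);
    const int oz = dil * (t / (k * k) - c0);
    gather_shift(X, Xs, nx, ny, nz, ox, oy, oz);
    dWt = Xs.t() * DY;  // cin x cout
    for (int ci = 0; ci < cin; ++ci)
      for (int co = 0; co < cout; ++co)
        dw(t + K * ci, co) = dWt(ci, co);
    if (need_dx) {
      for (int ci = 0; ci < cin; ++ci)
        for (int co = 0; co < cout; ++co)
          Wt(ci, co) = (float)w(t + K * ci, co);
      T = DY * Wt.t();  // nvox x cin, gradient before the shift
      scatter_add_shift(T, dX, nx, ny, nz, ox, oy, oz);
    }
  }

  NumericVector db(cout);
  for (int co = 0; co < cout; ++co)
    db[co] = arma::accu(arma::conv_to<arma::fvec>::from(DY.col(co)));

  List out = List::create(Named("dw") = dw, Named("db") = db);
  if (need_dx) {
    NumericVector dxv(nvox * (size_t)cin);
    const float *s = dX.memptr();
    double *d = dxv.begin();
    for (size_t i = 0; i < nvox * (size_t)cin; ++i) d[i] = s[i];
    dxv.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
    out["dx"] = dxv;
  }
  return out;
}
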