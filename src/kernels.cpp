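// Low-level numerical kernels: 3D same-padded convolution via im2col + BLAS,
// its gradients, and a separable Gaussian smoother with half-sample symmetric
// (mass-conserving) boundaries.
//
// Layout: activations are channels-last matrices (nvox*batch x channels) with
// voxels linearised column-major over (x, y, z), matching R's [d1, d2, d3]
// array storage. This makes every im2col column a set of contiguous x-runs
// (memcpy), and the convolution itself one GEMM per sample. Weights are
// (c_in * k1*k2*k3 x c_out) with row index c*K + (o1 + k1*(o2 + k2*o3)).
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col_one(const mat& X, uword s0, int d1, int d2, int d3,
                       int k1, int k2, int k3, mat& col) {
  const int h1 = k1 / 2, h2 = k2 / 2, h3 = k3 / 2;
  const uword cin = X.n_cols;
  const uword K = (uword)k1 * k2 * k3;
  for (uword c = 0; c < cin; ++c) {
    const double* xs = X.colptr(c) + s0;
    for (int o3 = 0; o3 < k3; ++o3) {
      const int s3 = o3 - h3;
      for (int o2 = 0; o2 < k2; ++o2) {
        const int s2 = o2 - h2;
        for (int o1 = 0; o1 < k1; ++o1) {
          const int s1 = o1 - h1;
          double* dst = col.colptr(c * K + (o1 + k1 * (o2 + k2 * o3)));
          for (int z = 0; z < d3; ++z) {
            const int zz = z + s3;
            for (int y = 0; y < d2; ++y) {
              const int yy = y + s2;
              double* drow = dst + (size_t)d1 * (y + (size_t)d2 * z);
              if (zz < 0 || zz >= d3 || yy < 0 || yy >= d2) {
                std::memset(drow, 0, sizeof(double) * d1);
                continue;
              }
              const double* srow = xs + (size_t)d1 * (yy + (size_t)d2 * zz);
              const int xlo = std::max(0, -s1), xhi = std::min(d1, d1 - s1);
              if (xlo > 0) std::memset(drow, 0, sizeof(double) * xlo);
              if (xhi > xlo)
                std::memcpy(drow + xlo, srow + xlo + s1,
                            sizeof(double) * (xhi - xlo));
              if (xhi < d1)
                std::memset(drow + xhi, 0, sizeof(double) * (d1 - xhi));
            }
          }
        }
      }
    }
  }
}

// transpose of im2col: scatter-add dcol runs back onto dX
static void col2im_one(const mat& dcol, uword s0, int d1, int d2, int d3,
                       int k1, int k2, int k3, mat& dX) {
  const int h1 = k1 / 2, h2 = k2 / 2, h3 = k3 / 2;
  const uword cin = dX.n_cols;
  const uword K = (uword)k1 * k2 * k3;
  for (uword c = 0; c < cin; ++c) {
    double* xs = dX.colptr(c) + s0;
    for (int o3 = 0; o3 < k3; ++o3) {
      const int s3 = o3 - h3;
      for (int o2 = 0; o2 < k2; ++o2) {
        const int s2 = o2 - h2;
        for (int o1 = 0; o1 < k1; ++o1) {
          const int s1 = o1 - h1;
          const double* src =
            dcol.colptr(c * K + (o1 + k1 * (o2 + k2 * o3)));
          for (int z = 0; z < d3; ++z) {
            const int zz = z + s3;
            if (zz < 0 || zz >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int yy = y + s2;
              if (yy < 0 || yy >= d2) continue;
              const double* srow = src + (size_t)d1 * (y + (size_t)d2 * z);
              double* drow = xs + (size_t)d1 * (yy + (size_t)d2 * zz) + s1;
              const int xlo = std::max(0, -s1), xhi = std::min(d1, d1 - s1);
              for (int x = xlo; x < xhi; ++x) drow[x] += srow[x];
            }
          }
        }
      }
    }
  }
}

// single-precision variant of im2col (GEMMs run ~2x faster in float and the
// network is trained by SGD, so float32 convolution accuracy is ample)
static void im2col_one_f(const fmat& X, uword s0, int d1, int d2, int d3,
                         int k1, int k2, int k3, fmat& col) {
  const int h1 = k1 / 2, h2 = k2 / 2, h3 = k3 / 2;
  const uword cin = X.n_cols;
  const uword K = (uword)k1 * k2 * k3;
  for (uword c = 0; c < cin; ++c) {
    const float* xs = X.colptr(c) + s0;
    for (int o3 = 0; o3 < k3; ++o3) {
      const int s3 = o3 - h3;
      for (int o2 = 0; o2 < k2; ++o2) {
        const int s2 = o2 - h2;
        for (int o1 = 0; o1 < k1; ++o1) {
          const int s1 = o1 - h1;
          float* dst = col.colptr(c * K + (o1 + k1 * (o2 + k2 * o3)));
          for (int z = 0; z < d3; ++z) {
            const int zz = z + s3;
            for (int y = 0; y < d2; ++y) {
              const int yy = y + s2;
              float* drow = dst + (size_t)d1 * (y + (size_t)d2 * z);
              if (zz < 0 || zz >= d3 || yy < 0 || yy >= d2) {
                std::memset(drow, 0, sizeof(float) * d1);
                continue;
              }
              const float* srow = xs + (size_t)d1 * (yy + (size_t)d2 * zz);
              const int xlo = std::max(0, -s1), xhi = std::min(d1, d1 - s1);
              if (xlo > 0) std::memset(drow, 0, sizeof(float) * xlo);
              if (xhi > xlo)
                std::memcpy(drow + xlo, srow + xlo + s1,
                            sizeof(float) * (xhi - xlo));
              if (xhi < d1)
                std::memset(drow + xhi, 0, sizeof(float) * (d1 - xhi));
            }
          }
        }
      }
    }
  }
}

static void col2im_one_f(const fmat& dcol, uword s0, int d1, int d2, int d3,
                         int k1, int k2, int k3, fmat& dX) {
  const int h1 = k1 / 2, h2 = k2 / 2, h3 = k3 / 2;
  const uword cin = dX.n_cols;
  const uword K = (uword)k1 * k2 * k3;
  for (uword c = 0; c < cin; ++c) {
    float* xs = dX.colptr(c) + s0;
    for (int o3 = 0; o3 < k3; ++o3) {
      const int s3 = o3 - h3;
      for (int o2 = 0; o2 < k2; ++o2) {
        const int s2 = o2 - h2;
        for (int o1 = 0; o1 < k1; ++o1) {
          const int s1 = o1 - h1;
          const float* src =
            dcol.colptr(c * K + (o1 + k1 * (o2 + k2 * o3)));
          for (int z = 0; z < d3; ++z) {
            const int zz = z + s3;
            if (zz < 0 || zz >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int yy = y + s2;
              if (yy < 0 || yy >= d2) continue;
              const float* srow = src + (size_t)d1 * (y + (size_t)d2 * z);
              float* drow = xs + (size_t)d1 * (yy + (size_t)d2 * zz) + s1;
              const int xlo = std::max(0, -s1), xhi = std::min(d1, d1 - s1);
              for (int x = xlo; x < xhi; ++x) drow[x] += srow[x];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv3d_fwd(const arma::mat& X, const arma::mat& W,
                     const arma::vec& b, const arma::ivec& dims,
                     const arma::ivec& kern, int batch,
                     bool single = false) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int k1 = kern[0], k2 = kern[1], k3 = kern[2];
  const uword cin = X.n_cols, cout = W.n_cols;
  const uword nvox = (uword)d1 * d2 * d3;
  if (X.n_rows != nvox * (uword)batch)
    Rcpp::stop("conv3d_fwd: X has %d rows, expected %d", (int)X.n_rows,
               (int)(nvox * batch));
  if (W.n_rows != cin * (uword)(k1 * k2 * k3))
    Rcpp::stop("conv3d_fwd: weight/kernel shape mismatch");
  if (single) {
    const fmat Xf = conv_to<fmat>::from(X);
    const fmat Wf = conv_to<fmat>::from(W);
    fmat Y(nvox * (uword)batch, cout);
    fmat col(nvox, cin * (uword)(k1 * k2 * k3));
    for (int s = 0; s < batch; ++s) {
      im2col_one_f(Xf, (uword)s * nvox, d1, d2, d3, k1, k2, k3, col);
      Y.rows((uword)s * nvox, (uword)(s + 1) * nvox - 1) = col * Wf;
    }
    mat Yd = conv_to<mat>::from(Y);
    Yd.each_row() += b.t();
    return Yd;
  }
  mat Y(nvox * (uword)batch, cout);
  mat col(nvox, cin * (uword)(k1 * k2 * k3));
  for (int s = 0; s < batch; ++s) {
    im2col_one(X, (uword)s * nvox, d1, d2, d3, k1, k2, k3, col);
    Y.rows((uword)s * nvox, (uword)(s + 1) * nvox - 1) = col * W;
  }
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bwd(const arma::mat& X, const arma::mat& W,
                      const arma::mat& dY, const arma::ivec& dims,
                      const arma::ivec& kern, int batch, bool need_dx,
                      bool single = false) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int k1 = kern[0], k2 = kern[1], k3 = kern[2];
  const uword cin = X.n_cols;
  const uword nvox = (uword)d1 * d2 * d3;
  if (single) {
    const fmat Xf = conv_to<fmat>::from(X);
    const fmat Wf = conv_to<fmat>::from(W);
    const fmat dYf = conv_to<fmat>::from(dY);
    fmat dW(W.n_rows, W.n_cols, fill::zeros);
    frowvec db = sum(dYf, 0);
    fmat dX;
    if (need_dx) dX.zeros(nvox * (uword)batch, cin);
    fmat col(nvox, cin * (uword)(k1 * k2 * k3));
    for (int s = 0; s < batch; ++s) {
      const uword r0 = (uword)s * nvox, r1 = (uword)(s + 1) * nvox - 1;
      im2col_one_f(Xf, r0, d1, d2, d3, k1, k2, k3, col);
      dW += col.t() * dYf.rows(r0, r1);
      if (need_dx) {
        const fmat dcol = dYf.rows(r0, r1) * Wf.t();
        col2im_one_f(dcol, r0, d1, d2, d3, k1, k2, k3, dX);
      }
    }
    return Rcpp::List::create(
      Rcpp::Named("dW") = conv_to<mat>::from(dW),
      Rcpp::Named("db") = conv_to<vec>::from(db.t()),
      Rcpp::Named("dX") = conv_to<mat>::from(dX));
  }
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  rowvec db = sum(dY, 0);
  mat dX;
  if (need_dx) dX.zeros(nvox * (uword)batch, cin);
  mat col(nvox, cin * (uword)(k1 * k2 * k3));
  for (int s = 0; s < batch; ++s) {
    const uword r0 = (uword)s * nvox, r1 = (uword)(s + 1) * nvox - 1;
    im2col_one(X, r0, d1, d2, d3, k1, k2, k3, col);
    dW += col.t() * dY.rows(r0, r1);
    if (need_dx) {
      const mat dcol = dY.rows(r0, r1) * W.t();
      col2im_one(dcol, r0, d1, d2, d3, k1, k2, k3, dX);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = vec(db.t()),
                            Rcpp::Named("dX") = dX);
}

// half-sample symmetric index: ...2 1 0 | 0 1 2 ... n-1 | n-1 n-2...
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static vec gauss_kernel(double sigma) {
  if (sigma <= 0) return vec{1.0};
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * (double)i * i / (sigma * sigma));
  return k / accu(k);
}

// [[Rcpp::export]]
arma::vec gauss_smooth3d(const arma::vec& x, const arma::ivec& dims,
                         const arma::vec& sigma_vox) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  vec cur = x, nxt(x.n_elem);
  const int d[3] = {d1, d2, d3};
  for (int ax = 0; ax < 3; ++ax) {
    const vec k = gauss_kernel(sigma_vox[ax]);
    const int r = ((int)k.n_elem - 1) / 2;
    if (r == 0 && k.n_elem == 1) continue;
    const int n = d[ax];
    const long s3 = (long)d1 * d2;
    const long stride = (ax == 0) ? 1L : (ax == 1 ? (long)d1 : s3);
    const int na = (ax == 0) ? d2 * d3 : (ax == 1 ? d1 * d3 : d1 * d2);
    for (int line = 0; line < na; ++line) {
      long base;
      if (ax == 0) {
        base = (long)line * d1;
      } else if (ax == 1) {
        int xx = line % d1, zz = line / d1;
        base = xx + (long)zz * s3;
      } else {
        base = line;  // line indexes the (x, y) plane
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j)
          acc += k(j + r) * cur[base + stride * reflect_idx(i + j, n)];
        nxt[base + stride * i] = acc;
      }
    }
    cur = nxt;
  }
  return cur;
}
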