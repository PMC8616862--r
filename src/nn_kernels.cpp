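// Volumetric CNN kernels: 3D convolution (im2col + GEMM), 2x2x2 max pooling,
// 2x2x2 transposed convolution, nearest-surface distances, and the
// CRC32 checksum used by the 16-bit PNG writer.
//
// Tensor layout throughout: column-major R arrays with dim (C, X, Y, Z, N),
// i.e. channels fastest.  All floating point is double.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Gather input patches for output voxels in the z-slab [z0, z1) into
// col (C*k^3 x Xo*Yo*(z1-z0)).  Fully-in-bounds windows take a fast path
// (one memcpy of C*k doubles per (dy, dz) tap row); border windows are
// zeroed per column (zero padding) and filled tap by tap.
static void im2col_slab(const double* x, int C, int X, int Y, int Z,
                        int k, int s, int p, int Xo, int Yo,
                        int z0, int z1, arma::mat& col) {
  const int nz = z1 - z0;
  const size_t rowlen = (size_t)C * k;
  for (int oz = 0; oz < nz; ++oz) {
    const int zbase = (z0 + oz) * s - p;
    const bool zin = zbase >= 0 && zbase + k <= Z;
    for (int oy = 0; oy < Yo; ++oy) {
      const int ybase = oy * s - p;
      const bool yin = ybase >= 0 && ybase + k <= Y;
      for (int ox = 0; ox < Xo; ++ox) {
        const int xbase = ox * s - p;
        double* cptr =
            col.colptr((size_t)ox + (size_t)Xo * (oy + (size_t)Yo * oz));
        if (zin && yin && xbase >= 0 && xbase + k <= X) {
          for (int dz = 0; dz < k; ++dz)
            for (int dy = 0; dy < k; ++dy)
              std::memcpy(
                  cptr + rowlen * (dy + (size_t)k * dz),
                  x + (size_t)C *
                          (xbase + (size_t)X * ((ybase + dy) +
                                                (size_t)Y * (zbase + dz))),
                  rowlen * sizeof(double));
          continue;
        }
        std::memset(cptr, 0, (size_t)C * k * k * k * sizeof(double));
        for (int dz = 0; dz < k; ++dz) {
          const int zz = zbase + dz;
          if (zz < 0 || zz >= Z) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int yy = ybase + dy;
            if (yy < 0 || yy >= Y) continue;
            const int xlo = std::max(0, -xbase);
            const int xhi = std::min(k, X - xbase);
            if (xlo >= xhi) continue;
            std::memcpy(
                cptr + (size_t)C * (xlo + k * (dy + (size_t)k * dz)),
                x + (size_t)C *
                        ((xbase + xlo) +
                         (size_t)X * (yy + (size_t)Y * zz)),
                (size_t)C * (xhi - xlo) * sizeof(double));
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col_slab (for input gradients).
static void col2im_slab(double* x, int C, int X, int Y, int Z,
                        int k, int s, int p, int Xo, int Yo,
                        int z0, int z1, const arma::mat& col) {
  const int nz = z1 - z0;
  const size_t rowlen = (size_t)C * k;
  for (int oz = 0; oz < nz; ++oz) {
    const int zbase = (z0 + oz) * s - p;
    const bool zin = zbase >= 0 && zbase + k <= Z;
    for (int oy = 0; oy < Yo; ++oy) {
      const int ybase = oy * s - p;
      const bool yin = ybase >= 0 && ybase + k <= Y;
      for (int ox = 0; ox < Xo; ++ox) {
        const int xbase = ox * s - p;
        const double* cptr =
            col.colptr((size_t)ox + (size_t)Xo * (oy + (size_t)Yo * oz));
        if (zin && yin && xbase >= 0 && xbase + k <= X) {
          for (int dz = 0; dz < k; ++dz)
            for (int dy = 0; dy < k; ++dy) {
              double* dst =
                  x + (size_t)C *
                          (xbase + (size_t)X * ((ybase + dy) +
                                                (size_t)Y * (zbase + dz)));
              const double* src = cptr + rowlen * (dy + (size_t)k * dz);
              for (size_t c = 0; c < rowlen; ++c) dst[c] += src[c];
            }
          continue;
        }
        for (int dz = 0; dz < k; ++dz) {
          const int zz = zbase + dz;
          if (zz < 0 || zz >= Z) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int yy = ybase + dy;
            if (yy < 0 || yy >= Y) continue;
            const int xlo = std::max(0, -xbase);
            const int xhi = std::min(k, X - xbase);
            for (int dx = xlo; dx < xhi; ++dx) {
              double* dst =
                  x + (size_t)C *
                          ((xbase + dx) + (size_t)X * (yy + (size_t)Y * zz));
              const double* src =
                  cptr + (size_t)C * (dx + k * (dy + (size_t)k * dz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// Pick a z-slab height keeping the im2col buffer under ~2e7 doubles.
static int slab_height(int C, int k, int Xo, int Yo, int Zo) {
  const double budget = 2e7;
  double per_slice = (double)C * k * k * k * Xo * Yo;
  int nz = (int)std::max(1.0, std::floor(budget / std::max(per_slice, 1.0)));
  return std::min(nz, Zo);
}

// shared per-tensor forward: y (Cout, Xo, Yo, Zo, N) = W * im2col(x) + b
static void conv_forward(const double* x, int C, int X, int Y, int Z, int N,
                         const arma::mat& W, const double* b,
                         int k, int s, int p, double* y) {
  const int Cout = W.n_rows;
  const int Xo = out_size(X, k, s, p), Yo = out_size(Y, k, s, p),
            Zo = out_size(Z, k, s, p);
  const int nzmax = slab_height(C, k, Xo, Yo, Zo);
  arma::mat col((size_t)C * k * k * k, (size_t)Xo * Yo * nzmax);
  arma::colvec bv(Cout, arma::fill::zeros);
  if (b) bv = arma::colvec(const_cast<double*>(b), Cout, false);
  const size_t xstride = (size_t)C * X * Y * Z;
  const size_t ystride = (size_t)Cout * Xo * Yo * Zo;
  for (int n = 0; n < N; ++n) {
    const double* xp = x + n * xstride;
    for (int z0 = 0; z0 < Zo; z0 += nzmax) {
      const int z1 = std::min(z0 + nzmax, Zo);
      const size_t ncols = (size_t)Xo * Yo * (z1 - z0);
      arma::mat colv(col.memptr(), col.n_rows, ncols, false, true);
      im2col_slab(xp, C, X, Y, Z, k, s, p, Xo, Yo, z0, z1, colv);
      arma::mat outv(y + n * ystride + (size_t)Cout * Xo * Yo * z0,
                     Cout, ncols, false, true);
      outv = W * colv;
      if (b) outv.each_col() += bv;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericMatrix Wr,
                             NumericVector b, int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3], N = xd[4];
  arma::mat W(Wr.begin(), Wr.nrow(), Wr.ncol(), false);
  const int Cout = W.n_rows;
  if ((int)W.n_cols != C * k * k * k)
    stop("weight matrix has %d columns, expected %d", (int)W.n_cols, C * k * k * k);
  const int Xo = out_size(X, k, s, p), Yo = out_size(Y, k, s, p),
            Zo = out_size(Z, k, s, p);
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("convolution output would be empty");
  NumericVector y((R_xlen_t)Cout * Xo * Yo * Zo * N);
  y.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo, N);
  conv_forward(x.begin(), C, X, Y, Z, N, W, b.begin(), k, s, p, y.begin());
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericMatrix Wr, NumericVector dy,
                    int k, int s, int p, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3], N = xd[4];
  arma::mat W(Wr.begin(), Wr.nrow(), Wr.ncol(), false);
  const int Cout = W.n_rows;
  const int Xo = out_size(X, k, s, p), Yo = out_size(Y, k, s, p),
            Zo = out_size(Z, k, s, p);
  arma::mat dW(Cout, (size_t)C * k * k * k, arma::fill::zeros);
  arma::colvec db(Cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((R_xlen_t)C * X * Y * Z * N);
    dx.attr("dim") = IntegerVector::create(C, X, Y, Z, N);
  }
  const int nzmax = slab_height(C, k, Xo, Yo, Zo);
  arma::mat col((size_t)C * k * k * k, (size_t)Xo * Yo * nzmax);
  const size_t xstride = (size_t)C * X * Y * Z;
  const size_t ystride = (size_t)Cout * Xo * Yo * Zo;
  const bool dx_by_corr = need_dx && s == 1;
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + n * xstride;
    for (int z0 = 0; z0 < Zo; z0 += nzmax) {
      const int z1 = std::min(z0 + nzmax, Zo);
      const size_t ncols = (size_t)Xo * Yo * (z1 - z0);
      arma::mat colv(col.memptr(), col.n_rows, ncols, false, true);
      im2col_slab(xp, C, X, Y, Z, k, s, p, Xo, Yo, z0, z1, colv);
      arma::mat dyv(const_cast<double*>(dy.begin()) + n * ystride +
                        (size_t)Cout * Xo * Yo * z0,
                    Cout, ncols, false, true);
      dW += dyv * colv.t();
      db += arma::sum(dyv, 1);
      if (need_dx && !dx_by_corr) {
        arma::mat dcol = W.t() * dyv;
        col2im_slab(dx.begin() + n * xstride, C, X, Y, Z, k, s, p, Xo, Yo,
                    z0, z1, dcol);
      }
    }
  }
  if (dx_by_corr) {
    // stride-1 input gradient as correlation of dy with spatially flipped
    // weights: dx = Wflip (*) dy at padding k - 1 - p (far less memory
    // traffic than col2im of W^T * dy)
    arma::mat Wflip(C, (size_t)Cout * k * k * k);
    for (int co = 0; co < Cout; ++co)
      for (int dz = 0; dz < k; ++dz)
        for (int dyy = 0; dyy < k; ++dyy)
          for (int dxx = 0; dxx < k; ++dxx)
            for (int c = 0; c < C; ++c)
              Wflip(c, (size_t)co +
                           (size_t)Cout *
                               ((k - 1 - dxx) +
                                (size_t)k * ((k - 1 - dyy) +
                                             (size_t)k * (k - 1 - dz)))) =
                  W(co, (size_t)c + (size_t)C * (dxx + k * (dyy + (size_t)k * dz)));
    conv_forward(dy.begin(), Cout, Xo, Yo, Zo, N, Wflip, nullptr,
                 k, 1, k - 1 - p, dx.begin());
  }
  NumericMatrix dWr(Cout, C * k * k * k);
  std::memcpy(dWr.begin(), dW.memptr(), dW.n_elem * sizeof(double));
  NumericVector dbr(db.begin(), db.end());
  if (need_dx)
    return List::create(_["dW"] = dWr, _["db"] = dbr, _["dx"] = dx);
  return List::create(_["dW"] = dWr, _["db"] = dbr);
}

// Max pooling, kernel 2, stride 2, floor semantics (trailing odd slice
// dropped).  Ties resolve to the first element in (dx, dy, dz) scan order.
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3], N = xd[4];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("input too small for 2x2x2 pooling");
  NumericVector y((R_xlen_t)C * Xo * Yo * Zo * N);
  y.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo, N);
  NumericVector idx((R_xlen_t)C * Xo * Yo * Zo * N);  // 0-based into x
  const size_t xstride = (size_t)C * X * Y * Z;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + n * xstride;
    for (int oz = 0; oz < Zo; ++oz)
      for (int oy = 0; oy < Yo; ++oy)
        for (int ox = 0; ox < Xo; ++ox)
          for (int c = 0; c < C; ++c, ++o) {
            double best = -HUGE_VAL;
            size_t besti = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const size_t i =
                      (size_t)c +
                      (size_t)C * ((2 * ox + dx) +
                                   (size_t)X * ((2 * oy + dy) +
                                                (size_t)Y * (2 * oz + dz)));
                  if (xp[i] > best) { best = xp[i]; besti = i; }
                }
            y[o] = best;
            idx[o] = (double)(besti + n * xstride);
          }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector idx, NumericVector dy,
                                IntegerVector xdim) {
  R_xlen_t nx = 1;
  for (int i = 0; i < xdim.size(); ++i) nx *= xdim[i];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t o = 0; o < dy.size(); ++o) dx[(R_xlen_t)idx[o]] += dy[o];
  return dx;
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping upsampling).
// W: (Cout*8 x Cin); row index = co + Cout*(dx + 2*(dy + 2*dz)).
// [[Rcpp::export]]
NumericVector cpp_convt3d_fwd(NumericVector x, NumericMatrix Wr,
                              NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3], N = xd[4];
  arma::mat W(Wr.begin(), Wr.nrow(), Wr.ncol(), false);
  const int Cout = W.n_rows / 8;
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y((R_xlen_t)Cout * Xo * Yo * Zo * N);
  y.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo, N);
  const size_t nvox = (size_t)X * Y * Z;
  const size_t xstride = (size_t)C * nvox;
  const size_t ystride = (size_t)Cout * Xo * Yo * Zo;
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + n * xstride, C, nvox,
                 false, true);
    arma::mat out = W * xm;  // (Cout*8) x nvox
    double* yp = y.begin() + n * ystride;
    size_t v = 0;
    for (int z = 0; z < Z; ++z)
      for (int yy = 0; yy < Y; ++yy)
        for (int xx = 0; xx < X; ++xx, ++v) {
          const double* src = out.colptr(v);
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                double* dst =
                    yp + (size_t)Cout *
                             ((2 * xx + dx) +
                              (size_t)Xo * ((2 * yy + dy) +
                                            (size_t)Yo * (2 * z + dz)));
                const double* s = src + (size_t)Cout * (dx + 2 * (dy + 2 * dz));
                for (int c = 0; c < Cout; ++c) dst[c] = s[c];
              }
        }
    // bias: every output voxel gets b once
    for (size_t vv = 0; vv < (size_t)Xo * Yo * Zo; ++vv) {
      double* dst = yp + (size_t)Cout * vv;
      for (int c = 0; c < Cout; ++c) dst[c] += b[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector x, NumericMatrix Wr, NumericVector dy,
                     bool need_dx) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3], N = xd[4];
  arma::mat W(Wr.begin(), Wr.nrow(), Wr.ncol(), false);
  const int Cout = W.n_rows / 8;
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const size_t nvox = (size_t)X * Y * Z;
  const size_t xstride = (size_t)C * nvox;
  const size_t ystride = (size_t)Cout * Xo * Yo * Zo;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::colvec db(Cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((R_xlen_t)C * X * Y * Z * N);
    dx.attr("dim") = IntegerVector::create(C, X, Y, Z, N);
  }
  arma::mat g(W.n_rows, nvox);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + n * ystride;
    size_t v = 0;
    for (int z = 0; z < Z; ++z)
      for (int yy = 0; yy < Y; ++yy)
        for (int xx = 0; xx < X; ++xx, ++v) {
          double* dst = g.colptr(v);
          for (int dz = 0; dz < 2; ++dz)
            for (int dy_ = 0; dy_ < 2; ++dy_)
              for (int dx_ = 0; dx_ < 2; ++dx_) {
                const double* src =
                    dyp + (size_t)Cout *
                              ((2 * xx + dx_) +
                               (size_t)Xo * ((2 * yy + dy_) +
                                             (size_t)Yo * (2 * z + dz)));
                double* d = dst + (size_t)Cout * (dx_ + 2 * (dy_ + 2 * dz));
                for (int c = 0; c < Cout; ++c) d[c] = src[c];
              }
        }
    arma::mat xm(const_cast<double*>(x.begin()) + n * xstride, C, nvox,
                 false, true);
    dW += g * xm.t();
    for (int c = 0; c < Cout; ++c) {
      double s = 0;
      for (size_t vv = 0; vv < (size_t)Xo * Yo * Zo; ++vv)
        s += dyp[(size_t)Cout * vv + c];
      db[c] += s;
    }
    if (need_dx) {
      arma::mat dxm(dx.begin() + n * xstride, C, nvox, false, true);
      dxm = W.t() * g;
    }
  }
  NumericMatrix dWr(W.n_rows, W.n_cols);
  std::memcpy(dWr.begin(), dW.memptr(), dW.n_elem * sizeof(double));
  NumericVector dbr(db.begin(), db.end());
  if (need_dx)
    return List::create(_["dW"] = dWr, _["db"] = dbr, _["dx"] = dx);
  return List::create(_["dW"] = dWr, _["db"] = dbr);
}

// Mean over rows of A of the Euclidean distance to the nearest row of B.
// [[Rcpp::export]]
double cpp_mean_nn_dist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  if (n == 0 || m == 0) stop("empty point set");
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = HUGE_VAL;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total / n;
}

// ---- checksums for the PNG writer ------------------------------------------

// [[Rcpp::export]]
double cpp_crc32(RawVector data, double init) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int j = 0; j < 8; ++j)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = (uint32_t)init ^ 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
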