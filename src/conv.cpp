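// Minimal 2-D convolution kernels for the CNN layers: im2col + BLAS gemm.
// Layouts follow R column-major arrays: images (H, W, C, N), filters
// (kh, kw, C, F).  Single-threaded; determinism matters more than speed here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix X (kh*kw*C x Ho*Wo) for image n.
static void im2col(const double* x, int H, int W, int C, int n,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, mat& X) {
  const double* xn = x + (size_t)H * W * C * n;
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int l = io + Ho * jo;
      double* col = X.colptr(l);
      for (int c = 0; c < C; ++c) {
        const double* xc = xn + (size_t)H * W * c;
        for (int dj = 0; dj < kw; ++dj) {
          const int jj = jo * stride - pad + dj;
          const bool jin = (jj >= 0 && jj < W);
          for (int di = 0; di < kh; ++di) {
            const int ii = io * stride - pad + di;
            const int row = di + kh * (dj + kw * c);
            col[row] = (jin && ii >= 0 && ii < H) ? xc[ii + (size_t)H * jj] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                               int stride, int pad) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) Rcpp::stop("channel mismatch between input and filters");
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) Rcpp::stop("filter larger than padded input");

  Rcpp::NumericVector y((size_t)Ho * Wo * F * N);
  y.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, F, N);
  const mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  mat X(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, Ho, Wo, X);
    mat Y = Wm.t() * X;  // F x (Ho*Wo)
    double* yn = y.begin() + (size_t)Ho * Wo * F * n;
    for (int f = 0; f < F; ++f)
      for (int l = 0; l < Ho * Wo; ++l)
        yn[l + (size_t)Ho * Wo * f] = Y(f, l);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                      Rcpp::NumericVector dy, int stride, int pad) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  const int K = kh * kw * C, L = Ho * Wo;

  Rcpp::NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  Rcpp::NumericVector dw((size_t)kh * kw * C * F);
  dw.attr("dim") = Rcpp::IntegerVector::create(kh, kw, C, F);
  const mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  mat dWm(dw.begin(), K, F, false, true);
  mat X(K, L), dY(F, L);

  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)L * F * n;
    for (int f = 0; f < F; ++f)
      for (int l = 0; l < L; ++l)
        dY(f, l) = dyn[l + (size_t)L * f];

    im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, Ho, Wo, X);
    dWm += X * dY.t();

    mat G = Wm * dY;  // K x L, scatter back (col2im)
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int l = io + Ho * jo;
        const double* col = G.colptr(l);
        for (int c = 0; c < C; ++c) {
          double* dxc = dxn + (size_t)H * W * c;
          for (int dj = 0; dj < kw; ++dj) {
            const int jj = jo * stride - pad + dj;
            if (jj < 0 || jj >= W) continue;
            for (int di = 0; di < kh; ++di) {
              const int ii = io * stride - pad + di;
              if (ii < 0 || ii >= H) continue;
              dxc[ii + (size_t)H * jj] += col[di + kh * (dj + kw * c)];
            }
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw);
}
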