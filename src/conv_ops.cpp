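// Convolution engine for the tile classifier.
//
// Feature maps are R arrays of dim (H, W, C, N); kernels are arrays of
// dim (k, k, C_in, C_out).  Convolutions are computed per sample by
// im2col + GEMM, which hands the heavy lifting to BLAS.  Everything is
// double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill `col` (k*k*Cin x Ho*Wo) with the patches of one sample.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int q = ho + Ho * wo;
      double* dst = col.colptr(q);
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x + (size_t)H * W * ci;
        for (int kw = 0; kw < k; ++kw) {
          const int w = wo * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = ho * stride - pad + kh;
            const int r = kh + k * (kw + k * ci);
            dst[r] = (h >= 0 && h < H && w >= 0 && w < W)
                       ? xc[h + (size_t)H * w] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of a column matrix back onto the (padded) input grid.
static void col2im_add(const arma::mat& col, int H, int W, int C,
                       int k, int stride, int pad, int Ho, int Wo,
                       double* gx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int q = ho + Ho * wo;
      const double* src = col.colptr(q);
      for (int ci = 0; ci < C; ++ci) {
        double* gc = gx + (size_t)H * W * ci;
        for (int kw = 0; kw < k; ++kw) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = ho * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            gc[h + (size_t)H * w] += src[kh + k * (kw + k * ci)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector kern,
                           Nullable<NumericVector> bias,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), kd = kern.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = kd[0], Ci = kd[2], Co = kd[3];
  if (kd[1] != k) stop("kernel must be square");
  if (Ci != C) stop("channel mismatch between input and kernel");
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("input too small for kernel/stride/padding");

  NumericVector out((size_t)Ho * Wo * Co * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);

  const arma::mat Wm(const_cast<double*>(kern.begin()), k * k * Ci, Co,
                     false, true);
  arma::rowvec b;
  if (bias.isNotNull()) {
    NumericVector bv(bias);
    b = arma::rowvec(bv.begin(), Co);
  }
  arma::mat col(k * k * Ci, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
           Ho, Wo, col);
    arma::mat O(out.begin() + (size_t)Ho * Wo * Co * n,
                (size_t)Ho * Wo, Co, false, true);
    O = col.t() * Wm;
    if (bias.isNotNull()) O.each_row() += b;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector x, NumericVector kern, NumericVector gout,
                  int stride, int pad, bool has_bias, bool want_gx) {
  IntegerVector xd = x.attr("dim"), kd = kern.attr("dim"),
                gd = gout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = kd[0], Ci = kd[2], Co = kd[3];
  const int Ho = gd[0], Wo = gd[1];

  NumericVector gx(want_gx ? (size_t)H * W * C * N : 0);
  if (want_gx) gx.attr("dim") = xd;
  NumericVector gw((size_t)k * k * Ci * Co);
  gw.attr("dim") = kd;
  NumericVector gb(Co);

  const arma::mat Wm(const_cast<double*>(kern.begin()), k * k * Ci, Co,
                     false, true);
  arma::mat Gw(gw.begin(), k * k * Ci, Co, false, true);
  arma::rowvec Gb(Co, arma::fill::zeros);
  arma::mat col(k * k * Ci, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const arma::mat G(const_cast<double*>(gout.begin())
                        + (size_t)Ho * Wo * Co * n,
                      (size_t)Ho * Wo, Co, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
           Ho, Wo, col);
    Gw += col * G;
    if (has_bias) Gb += arma::sum(G, 0);
    if (want_gx) {
      arma::mat colG = Wm * G.t();
      col2im_add(colG, H, W, C, k, stride, pad, Ho, Wo,
                 gx.begin() + (size_t)H * W * C * n);
    }
  }
  if (has_bias) std::copy(Gb.begin(), Gb.end(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
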