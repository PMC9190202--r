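// Fused per-channel kernels for the (H, W, C, N) feature-map layout.
// These exist to keep batch-norm and attention out of R's allocator on
// the training hot path.

#include <Rcpp.h>
using namespace Rcpp;

static inline void get_dims(const NumericVector& x, int& HW, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  HW = d[0] * d[1];
  C = d[2];
  N = d[3];
}

// Per-channel, per-sample sums of x (or of x*y when y is given):
// returns a C x N matrix without materializing x*y.
// [[Rcpp::export(name = ".cpp_ch_sum")]]
NumericMatrix cpp_ch_sum(NumericVector x, Nullable<NumericVector> y) {
  int HW, C, N;
  get_dims(x, HW, C, N);
  NumericMatrix out(C, N);
  const double* px = x.begin();
  if (y.isNotNull()) {
    NumericVector yv(y);
    const double* py = yv.begin();
    for (R_xlen_t j = 0; j < (R_xlen_t)C * N; ++j) {
      double s = 0;
      const double* a = px + j * HW;
      const double* b = py + j * HW;
      for (int i = 0; i < HW; ++i) s += a[i] * b[i];
      out[j] = s;
    }
  } else {
    for (R_xlen_t j = 0; j < (R_xlen_t)C * N; ++j) {
      double s = 0;
      const double* a = px + j * HW;
      for (int i = 0; i < HW; ++i) s += a[i];
      out[j] = s;
    }
  }
  return out;
}

// y = x * scale[c] + shift[c]; scale/shift have length C (shared over
// samples) or C*N (per sample).
// [[Rcpp::export(name = ".cpp_ch_affine")]]
NumericVector cpp_ch_affine(NumericVector x, NumericVector scale,
                            NumericVector shift) {
  int HW, C, N;
  get_dims(x, HW, C, N);
  NumericVector out(no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  const bool perSample = scale.size() == (R_xlen_t)C * N;
  const bool perSampleShift = shift.size() == (R_xlen_t)C * N;
  for (R_xlen_t j = 0; j < (R_xlen_t)C * N; ++j) {
    const double a = perSample ? scale[j] : scale[j % C];
    const double b = perSampleShift ? shift[j] : shift[j % C];
    const double* src = x.begin() + j * HW;
    double* dst = out.begin() + j * HW;
    for (int i = 0; i < HW; ++i) dst[i] = src[i] * a + b;
  }
  return out;
}

// Fused batch-norm backward: given upstream grad gy, cached xhat and
// istd, and gamma, returns gx plus the gamma/beta grads in one pass.
// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector gy, NumericVector xhat, NumericVector gamma,
                NumericVector istd) {
  int HW, C, N;
  get_dims(gy, HW, C, N);
  const double m = (double)HW * N;
  NumericVector s1(C), s2(C), ggam(C), gbet(C);
  // first pass: per-channel sums of gxhat and gxhat*xhat, plus grads
  for (R_xlen_t j = 0; j < (R_xlen_t)C * N; ++j) {
    const int c = j % C;
    const double* a = gy.begin() + j * HW;
    const double* h = xhat.begin() + j * HW;
    double t1 = 0, t2 = 0;
    for (int i = 0; i < HW; ++i) {
      t1 += a[i];
      t2 += a[i] * h[i];
    }
    s1[c] += t1 * gamma[c];
    s2[c] += t2 * gamma[c];
    gbet[c] += t1;
    ggam[c] += t2;
  }
  NumericVector gx(no_init(gy.size()));
  gx.attr("dim") = gy.attr("dim");
  for (R_xlen_t j = 0; j < (R_xlen_t)C * N; ++j) {
    const int c = j % C;
    const double* a = gy.begin() + j * HW;
    const double* h = xhat.begin() + j * HW;
    double* d = gx.begin() + j * HW;
    const double k1 = gamma[c], k2 = s2[c] / m, k3 = s1[c] / m,
                 ks = istd[c];
    for (int i = 0; i < HW; ++i) {
      d[i] = ks * (a[i] * k1 - h[i] * k2 - k3);
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggam, _["gbeta"] = gbet);
}

// ReLU forward (new array) and masked backward (gy where ref > 0).
// [[Rcpp::export(name = ".cpp_relu")]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector out(no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] > 0 ? x[i] : 0;
  return out;
}

// [[Rcpp::export(name = ".cpp_mask_pos")]]
NumericVector cpp_mask_pos(NumericVector gy, NumericVector ref) {
  NumericVector out(no_init(gy.size()));
  out.attr("dim") = gy.attr("dim");
  for (R_xlen_t i = 0; i < gy.size(); ++i) out[i] = ref[i] > 0 ? gy[i] : 0;
  return out;
}

// Elementwise sum of two or three equal-shaped arrays in one pass.
// [[Rcpp::export(name = ".cpp_add")]]
NumericVector cpp_add(NumericVector a, NumericVector b,
                      Nullable<NumericVector> c) {
  NumericVector out(no_init(a.size()));
  out.attr("dim") = a.attr("dim");
  if (c.isNotNull()) {
    NumericVector cv(c);
    for (R_xlen_t i = 0; i < a.size(); ++i) out[i] = a[i] + b[i] + cv[i];
  } else {
    for (R_xlen_t i = 0; i < a.size(); ++i) out[i] = a[i] + b[i];
  }
  return out;
}

// Per-channel first and second moments in a single read of x:
// returns list(s1 = rowSums over (HW, N), s2 = sums of squares), each
// length C.
// [[Rcpp::export(name = ".cpp_ch_moments")]]
List cpp_ch_moments(NumericVector x) {
  int HW, C, N;
  get_dims(x, HW, C, N);
  NumericVector s1(C), s2(C);
  for (R_xlen_t j = 0; j < (R_xlen_t)C * N; ++j) {
    const int c = j % C;
    const double* a = x.begin() + j * HW;
    double t1 = 0, t2 = 0;
    for (int i = 0; i < HW; ++i) {
      t1 += a[i];
      t2 += a[i] * a[i];
    }
    s1[c] += t1;
    s2[c] += t2;
  }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}

// Batch-norm forward in one read of x: xhat = (x - mu) * istd and
// y = xhat * gamma + beta.
// [[Rcpp::export(name = ".cpp_bn_apply")]]
List cpp_bn_apply(NumericVector x, NumericVector mu, NumericVector istd,
                  NumericVector gamma, NumericVector beta) {
  int HW, C, N;
  get_dims(x, HW, C, N);
  NumericVector xhat(no_init(x.size())), y(no_init(x.size()));
  xhat.attr("dim") = x.attr("dim");
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t j = 0; j < (R_xlen_t)C * N; ++j) {
    const int c = j % C;
    const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    const double* src = x.begin() + j * HW;
    double* ph = xhat.begin() + j * HW;
    double* py = y.begin() + j * HW;
    for (int i = 0; i < HW; ++i) {
      const double h = (src[i] - m) * is;
      ph[i] = h;
      py[i] = h * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// y = max(0, x * scale[c or c,n]): channel gate and ReLU in one pass.
// [[Rcpp::export(name = ".cpp_ch_mul_relu")]]
NumericVector cpp_ch_mul_relu(NumericVector x, NumericVector scale) {
  int HW, C, N;
  get_dims(x, HW, C, N);
  NumericVector out(no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  const bool perSample = scale.size() == (R_xlen_t)C * N;
  for (R_xlen_t j = 0; j < (R_xlen_t)C * N; ++j) {
    const double a = perSample ? scale[j] : scale[j % C];
    const double* src = x.begin() + j * HW;
    double* dst = out.begin() + j * HW;
    for (int i = 0; i < HW; ++i) {
      const double v = src[i] * a;
      dst[i] = v > 0 ? v : 0;
    }
  }
  return out;
}

// out = a * sa[c,n] + b * sb[c,n] in one pass (attention backward).
// [[Rcpp::export(name = ".cpp_two_affine_add")]]
NumericVector cpp_two_affine_add(NumericVector a, NumericVector sa,
                                 NumericVector b, NumericVector sb) {
  int HW, C, N;
  get_dims(a, HW, C, N);
  NumericVector out(no_init(a.size()));
  out.attr("dim") = a.attr("dim");
  const bool psa = sa.size() == (R_xlen_t)C * N;
  const bool psb = sb.size() == (R_xlen_t)C * N;
  for (R_xlen_t j = 0; j < (R_xlen_t)C * N; ++j) {
    const double ka = psa ? sa[j] : sa[j % C];
    const double kb = psb ? sb[j] : sb[j % C];
    const double* pa = a.begin() + j * HW;
    const double* pb = b.begin() + j * HW;
    double* dst = out.begin() + j * HW;
    for (int i = 0; i < HW; ++i) dst[i] = pa[i] * ka + pb[i] * kb;
  }
  return out;
}
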