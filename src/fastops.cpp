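// Hot inner loops of the conv-net engine: im2col/col2im gathers and the
// fused Adam update. Everything else stays in R on top of BLAS.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x: array (C, L, B) flattened column-major; returns (C*k, Lout*B) matrix
// with column (b*Lout + t) holding the k taps of the receptive field at
// output position t (stride/pad applied), channels fastest.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int L, int B, int k,
                         int stride, int pad, int Lout) {
  NumericMatrix out(C * k, Lout * B);
  const double* px = x.begin();
  double* po = out.begin();
  const size_t collen = (size_t)C * k;
  for (int b = 0; b < B; ++b) {
    const double* xb = px + (size_t)b * C * L;
    for (int t = 0; t < Lout; ++t) {
      double* col = po + ((size_t)b * Lout + t) * collen;
      const int start = t * stride - pad;
      for (int j = 0; j < k; ++j) {
        const int p = start + j;
        double* dst = col + (size_t)j * C;
        if (p < 0 || p >= L) {
          std::fill(dst, dst + C, 0.0);
        } else {
          const double* src = xb + (size_t)p * C;
          std::copy(src, src + C, dst);
        }
      }
    }
  }
  return out;
}

// adjoint of im2col_cpp: scatter-add a (C*k, Lout*B) gradient back to the
// (C, L, B) input layout.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcol, int C, int L, int B, int k,
                         int stride, int pad, int Lout) {
  NumericVector dx((size_t)C * L * B);   // zero-initialised
  double* pdx = dx.begin();
  const double* pc = dcol.begin();
  const size_t collen = (size_t)C * k;
  for (int b = 0; b < B; ++b) {
    double* xb = pdx + (size_t)b * C * L;
    for (int t = 0; t < Lout; ++t) {
      const double* col = pc + ((size_t)b * Lout + t) * collen;
      const int start = t * stride - pad;
      for (int j = 0; j < k; ++j) {
        const int p = start + j;
        if (p < 0 || p >= L) continue;
        double* dst = xb + (size_t)p * C;
        const double* src = col + (size_t)j * C;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, L, B);
  return dx;
}

// One fused Adam step. m and v are updated in place (the optimizer state is
// solely owned by the training loop); the returned vector is the new weight
// tensor. Positions with zero gradient, zero moments and zero weight stay
// exactly zero, which keeps pruning masks intact.
// [[Rcpp::export]]
NumericVector adam_fused(NumericVector w, NumericVector g, NumericVector m,
                         NumericVector v, double lr, double beta1,
                         double beta2, double bc1, double bc2, double eps) {
  const R_xlen_t n = w.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam_fused: length mismatch");
  NumericVector out(no_init(n));
  const double* pw = w.begin();
  const double* pg = g.begin();
  double* pm = m.begin();
  double* pv = v.begin();
  double* po = out.begin();
  const double a1 = 1.0 - beta1, a2 = 1.0 - beta2;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    const double mi = beta1 * pm[i] + a1 * gi;
    const double vi = beta2 * pv[i] + a2 * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    po[i] = pw[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
  out.attr("dim") = w.attr("dim");
  return out;
}
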