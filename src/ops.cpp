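#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam step over a flat parameter list. Each element of
// `params`, `m` and `v` is updated in place (the caller owns all three and
// keeps the nested parameter view aliased to `params` deliberately).
// [[Rcpp::export]]
void adam_step_inplace(List params, List grads, List m, List v,
                       double lr, double beta1, double beta2, double eps,
                       int t) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (int k = 0; k < params.size(); ++k) {
    NumericVector p = params[k];
    NumericVector g = grads[k];
    NumericVector mk = m[k];
    NumericVector vk = v[k];
    const R_xlen_t n = p.size();
    double *pp = REAL(p), *gg = REAL(g), *mm = REAL(mk), *vv = REAL(vk);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double gi = gg[i];
      mm[i] = beta1 * mm[i] + (1.0 - beta1) * gi;
      vv[i] = beta2 * vv[i] + (1.0 - beta2) * gi * gi;
      pp[i] -= lr * (mm[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
    }
  }
}

// In-place ReLU; returns its (modified) argument.
// [[Rcpp::export]]
NumericVector relu_inplace(NumericVector x) {
  double *px = REAL(x);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (px[i] < 0.0) px[i] = 0.0;
  return x;
}

// In-place ReLU backward: dA *= (pre > 0). `pre` holds the pre-activations.
// [[Rcpp::export]]
void relu_backward_inplace(NumericVector dA, NumericVector pre) {
  double *pd = REAL(dA);
  const double *pp = REAL(pre);
  const R_xlen_t n = dA.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (pp[i] <= 0.0) pd[i] = 0.0;
}
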