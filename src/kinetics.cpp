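#include <Rcpp.h>
using namespace Rcpp;

// Exponential-decay convolution integrals on a uniform fine time grid:
//   I_k(t_j) = int_0^{t_j} cp(tau) * exp(-kep_k (t_j - tau)) dtau
// computed with the unconditionally stable trapezoidal recursion
//   I(t+dt) = I(t) e^{-kep dt} + dt/2 (cp(t+dt) + cp(t) e^{-kep dt}).
// Returns an n x K matrix (time x kep).
// [[Rcpp::export]]
NumericMatrix cpp_exp_conv(NumericVector cp, double dt, NumericVector kep) {
  const int n = cp.size(), K = kep.size();
  NumericMatrix out(n, K);
  for (int k = 0; k < K; ++k) {
    const double e = std::exp(-kep[k] * dt);
    double acc = 0.0;
    out(0, k) = 0.0;
    for (int j = 1; j < n; ++j) {
      acc = acc * e + 0.5 * dt * (cp[j] + cp[j - 1] * e);
      out(j, k) = acc;
    }
  }
  return out;
}
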