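#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a 2-state HMM, summed over independent
// segments.  logdens: n x 2 per-observation log emission densities;
// seg: 1-based segment start indices (first element 1); delta: initial state
// distribution applied at each segment start; Gamma: 2x2 transition matrix.
// [[Rcpp::export(name = ".hmm_forward_ll")]]
double hmm_forward_ll(const NumericMatrix &logdens, const IntegerVector &seg,
                      const NumericVector &delta, const NumericMatrix &Gamma) {
  const int n = logdens.nrow();
  std::vector<bool> is_start(n, false);
  for (int k = 0; k < seg.size(); ++k) is_start[seg[k] - 1] = true;

  double ll = 0.0, a0 = 0.0, a1 = 0.0;
  for (int t = 0; t < n; ++t) {
    double m = std::max(logdens(t, 0), logdens(t, 1));
    double d0 = std::exp(logdens(t, 0) - m);
    double d1 = std::exp(logdens(t, 1) - m);
    double b0, b1;
    if (is_start[t]) {
      b0 = delta[0] * d0;
      b1 = delta[1] * d1;
    } else {
      b0 = (a0 * Gamma(0, 0) + a1 * Gamma(1, 0)) * d0;
      b1 = (a0 * Gamma(0, 1) + a1 * Gamma(1, 1)) * d1;
    }
    double c = b0 + b1;
    if (!(c > 0.0) || !std::isfinite(c)) return R_NegInf;
    ll += std::log(c) + m;
    a0 = b0 / c; a1 = b1 / c;
  }
  return ll;
}
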