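#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the compartment model ODE system.
//
// The state is a concentration vector (mol/cm^3 of the owning
// compartment's reference volume).  The derivative combines
//  - irreversible bilinear association fluxes (a + b -> p),
//  - general linear terms dy[tgt] += coef * y[src] (dissociation,
//    internalization, trafficking, clearance, degradation, transport,
//    lymph), where terms flagged vs = 1 are additionally multiplied by
//    the current tumor volume (blood-side fluxes across the growing
//    tumor interface),
//  - zero-order sources (secretion, synthesis, receptor insertion,
//    drug infusion), vs = 1 again scaling with tumor volume,
//  - first-order dilution of tumor-compartment species at the
//    exponential growth rate g, so that amounts are conserved under
//    pure growth.
//
// Tumor volume is V(t) = vt0 * exp(g * (t - t0)) within a segment.
// All index vectors are 0-based.
// [[Rcpp::export]]
NumericVector rhs_core(double t, NumericVector y,
                       IntegerVector bi_a, IntegerVector bi_b,
                       IntegerVector bi_p, NumericVector bi_k,
                       IntegerVector l_src, IntegerVector l_tgt,
                       NumericVector l_coef, IntegerVector l_vs,
                       IntegerVector s_tgt, NumericVector s_rate,
                       IntegerVector s_vs,
                       IntegerVector dil_idx,
                       double g, double vt0, double t0) {
  const int n = y.size();
  NumericVector dy(n);
  const double vt = vt0 * std::exp(g * (t - t0));

  const int nb = bi_a.size();
  for (int j = 0; j < nb; ++j) {
    const double f = bi_k[j] * y[bi_a[j]] * y[bi_b[j]];
    dy[bi_a[j]] -= f;
    dy[bi_b[j]] -= f;
    dy[bi_p[j]] += f;
  }

  const int nl = l_src.size();
  for (int j = 0; j < nl; ++j) {
    double c = l_coef[j];
    if (l_vs[j]) c *= vt;
    dy[l_tgt[j]] += c * y[l_src[j]];
  }

  const int ns = s_tgt.size();
  for (int j = 0; j < ns; ++j) {
    double r = s_rate[j];
    if (s_vs[j]) r *= vt;
    dy[s_tgt[j]] += r;
  }

  if (g != 0.0) {
    const int nd = dil_idx.size();
    for (int j = 0; j < nd; ++j)
      dy[dil_idx[j]] -= g * y[dil_idx[j]];
  }
  return dy;
}
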