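#include <Rcpp.h>
using namespace Rcpp;

// One single-site Gibbs sweep over the location equations, in equation
// order. `Cp`, `Ci`, `Cx` are the column slots of the (general, both
// triangles stored) sparse symmetric coefficient matrix; by symmetry a
// column is the matching row. Draws from each scalar full conditional
// N((rhs_e - C[e,-e] theta[-e]) / C[e,e], 1 / C[e,e]) using R's RNG.
// [[Rcpp::export]]
NumericVector gibbs_location_sweep(IntegerVector Cp, IntegerVector Ci,
                                   NumericVector Cx, NumericVector rhs,
                                   NumericVector theta) {
  int n = rhs.size();
  NumericVector th = clone(theta);
  for (int e = 0; e < n; ++e) {
    double dot = 0.0, d = 0.0;
    for (int idx = Cp[e]; idx < Cp[e + 1]; ++idx) {
      int r = Ci[idx];
      if (r == e) d = Cx[idx];
      else dot += Cx[idx] * th[r];
    }
    if (d <= 0.0) stop("zero diagonal in Gibbs sweep at equation %d", e + 1);
    double m = (rhs[e] - dot) / d;
    th[e] = m + norm_rand() / std::sqrt(d);
  }
  return th;
}
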