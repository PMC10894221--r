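#include <Rcpp.h>
using namespace Rcpp;

// Prominence of each candidate local maximum: height above the higher of
// the two valleys separating it from taller terrain on either side.
// [[Rcpp::export]]
NumericVector peak_prominences_cpp(NumericVector v, IntegerVector idx) {
  const int n = v.size();
  const int m = idx.size();
  NumericVector prom(m);
  for (int q = 0; q < m; ++q) {
    const int p = idx[q] - 1; // 1-based from R
    const double h = v[p];
    double base_l = R_PosInf, base_r = R_PosInf;
    // walk left to the nearest strictly higher sample, tracking the minimum
    for (int i = p - 1; i >= 0; --i) {
      if (v[i] > h) break;
      if (v[i] < base_l) base_l = v[i];
    }
    for (int i = p + 1; i < n; ++i) {
      if (v[i] > h) break;
      if (v[i] < base_r) base_r = v[i];
    }
    prom[q] = h - std::max(base_l == R_PosInf ? R_NegInf : base_l,
                           base_r == R_PosInf ? R_NegInf : base_r);
  }
  return prom;
}
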