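#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquad sections (direct form II transposed), zero initial
// conditions, applied column-wise. sos rows are (b0, b1, b2, a0, a1, a2)
// with a0 == 1.
// [[Rcpp::export]]
NumericMatrix sos_filter_cpp(NumericMatrix sos, NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol(), ns = sos.nrow();
  NumericMatrix y = clone(x);
  for (int j = 0; j < m; ++j) {
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      double z1 = 0.0, z2 = 0.0;
      for (int t = 0; t < n; ++t) {
        const double xt = y(t, j);
        const double yt = b0 * xt + z1;
        z1 = b1 * xt - a1 * yt + z2;
        z2 = b2 * xt - a2 * yt;
        y(t, j) = yt;
      }
    }
  }
  return y;
}
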