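#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. a[0] must be 1. zi (length
// max(na,nb)-1) gives the initial filter state, scaled by the caller.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(na, nb);
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(n - 1, 0.0);
  if (zi.size() == (R_xlen_t)(n - 1))
    for (int i = 0; i < n - 1; ++i) z[i] = zi[i];
  R_xlen_t N = x.size();
  NumericVector y(N);
  for (R_xlen_t i = 0; i < N; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < n - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[n - 2] = bb[n - 1] * xi - aa[n - 1] * yi;
    y[i] = yi;
  }
  return y;
}
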