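#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state.
// b, a: coefficients with a[0] == 1; zi: length max(na, nb) - 1.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nfilt = std::max(na, nb);
  int n = x.size();
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nfilt, 0.0);
  for (int i = 0; i < nfilt - 1 && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int m = 0; m < n; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + z[0];
    for (int i = 1; i < nfilt; ++i)
      z[i - 1] = bb[i] * xm + z[i] - aa[i] * ym;
    y[m] = ym;
  }
  return y;
}
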