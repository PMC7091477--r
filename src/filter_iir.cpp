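#include <Rcpp.h>
using namespace Rcpp;

// Direct form II transposed IIR filter, a[0] assumed 1 (as from a
// normalised Butterworth design).
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = bb[0] * xt + z[0];
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}
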