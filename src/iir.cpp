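#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with explicit initial state.
// b, a: transfer-function coefficients (a[0] must be 1 after normalisation);
// zi: initial delay-line state of length max(length(a), length(b)) - 1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nz = std::max(na, nb) - 1;
  if (zi.size() != nz) stop("zi must have length %d", nz);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (aa[0] != 1.0) {
    if (aa[0] == 0.0) stop("a[0] must be non-zero");
    for (int i = 0; i <= nz; ++i) { bb[i] /= a[0]; aa[i] /= a[0]; }
  }
  for (int i = 0; i < nz; ++i) z[i] = zi[i];
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
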