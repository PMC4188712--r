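#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter applied down each column of X.
// b, a are filter coefficients (a[0] must be 1), zi the per-unit initial
// state (scaled by the first sample of each column before filtering).
// [[Rcpp::export(name = ".iir_filter_mat")]]
NumericMatrix iir_filter_mat(NumericVector b, NumericVector a,
                             NumericMatrix X, NumericVector zi) {
  const int n = X.nrow(), m = X.ncol();
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na) - 1;
  NumericMatrix Y(n, m);
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(ns);
  const double *bp = bb.data(), *ap = aa.data();
  double *zp = z.data();
  for (int j = 0; j < m; ++j) {
    const double *xc = &X[(R_xlen_t)j * n];
    double *yc = &Y[(R_xlen_t)j * n];
    const double x0 = xc[0];
    for (int k = 0; k < ns; ++k) zp[k] = zi[k] * x0;
    for (int i = 0; i < n; ++i) {
      const double x = xc[i];
      const double y = bp[0] * x + zp[0];
      for (int k = 0; k < ns - 1; ++k)
        zp[k] = bp[k + 1] * x + zp[k + 1] - ap[k + 1] * y;
      zp[ns - 1] = bp[ns] * x - ap[ns] * y;
      yc[i] = y;
    }
  }
  return Y;
}
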