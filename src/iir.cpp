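#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter applied down the rows (samples) of
// each column (channel) of X, with per-channel initial state Zi
// (n_state x n_channels). Coefficients must be normalized so a[0] == 1.
// [[Rcpp::export(name = ".iir_df2t")]]
NumericMatrix iir_df2t(NumericVector b, NumericVector a,
                       NumericMatrix X, NumericMatrix Zi) {
  const int n = X.nrow(), nch = X.ncol();
  const int k = a.size() - 1;  // state length; b padded to same length
  NumericMatrix Y(n, nch);
  std::vector<double> z(k);
  for (int ch = 0; ch < nch; ++ch) {
    for (int j = 0; j < k; ++j) z[j] = Zi(j, ch);
    for (int i = 0; i < n; ++i) {
      const double x = X(i, ch);
      const double y = b[0] * x + z[0];
      for (int j = 0; j < k - 1; ++j)
        z[j] = b[j + 1] * x + z[j + 1] - a[j + 1] * y;
      z[k - 1] = b[k] * x - a[k] * y;
      Y(i, ch) = y;
    }
  }
  return Y;
}
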