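#include <Rcpp.h>
using namespace Rcpp;

// Compose one rendered trial in a single pass:
//   out[i, t] = max(0, noiseless[i, t] + base[i] * (osc[t] + sd * N(0,1)))
// Uses R's RNG (draw order: t outer, i inner — identical to filling an
// [np x nt] matrix from a single rnorm vector column-major).
// [[Rcpp::export(name = ".render_noise")]]
NumericMatrix render_noise(NumericMatrix noiseless, NumericVector base,
                           NumericVector osc, double sd) {
  const int np = noiseless.nrow();
  const int nt = noiseless.ncol();
  NumericMatrix out(np, nt);
  const bool draw = sd > 0;
  GetRNGstate();
  for (int t = 0; t < nt; ++t) {
    const double o = osc[t];
    for (int i = 0; i < np; ++i) {
      double v = noiseless(i, t) +
        base[i] * (o + (draw ? sd * norm_rand() : 0.0));
      out(i, t) = v < 0 ? 0 : v;
    }
  }
  PutRNGstate();
  return out;
}

// Direct-form-II-transposed IIR filtering of many series at once.
// X is [n_series x n_time] (series along rows); zi holds the steady-state
// initial conditions for a unit input level, scaled per series by the
// first sample. Coefficients must already be normalized to a[0] = 1.
// [[Rcpp::export(name = ".iir_df2t_rows")]]
NumericMatrix iir_df2t_rows(NumericVector b, NumericVector a,
                            NumericMatrix X, NumericVector zi) {
  const int n = b.size();          // filter length (== a.size())
  const int np = X.nrow();
  const int nt = X.ncol();
  NumericMatrix Y(np, nt);
  NumericMatrix Z(np, n - 1);
  for (int i = 0; i < np; ++i) {
    for (int k = 0; k < n - 1; ++k) Z(i, k) = zi[k] * X(i, 0);
  }
  for (int t = 0; t < nt; ++t) {
    for (int i = 0; i < np; ++i) {
      const double xt = X(i, t);
      const double yt = b[0] * xt + Z(i, 0);
      for (int k = 0; k < n - 2; ++k) {
        Z(i, k) = b[k + 1] * xt + Z(i, k + 1) - a[k + 1] * yt;
      }
      Z(i, n - 2) = b[n - 1] * xt - a[n - 1] * yt;
      Y(i, t) = yt;
    }
  }
  return Y;
}
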