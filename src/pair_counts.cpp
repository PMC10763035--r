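#include <Rcpp.h>
using namespace Rcpp;

// Pair classification for the continuous concordance index.
// Over all unordered pairs (i, j): pairs tied on the prediction are
// ineligible (tie_x); eligible pairs are concordant when
// (yhat_i - yhat_j) * (y_i - y_j) > 0, discordant when < 0, and tie_y when
// the observed values are equal. Counts are doubles: n * (n - 1) / 2
// overflows 32-bit integers near n = 2^16.
// [[Rcpp::export]]
NumericVector pair_counts(NumericVector yhat, NumericVector y) {
  R_xlen_t n = yhat.size();
  if (y.size() != n) stop("yhat and y lengths differ");
  double conc = 0.0, disc = 0.0, tie_y = 0.0, tie_x = 0.0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    double xi = yhat[i], yi = y[i];
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double dx = xi - yhat[j];
      if (dx == 0.0) { tie_x += 1.0; continue; }
      double dy = yi - y[j];
      if (dy == 0.0) tie_y += 1.0;
      else if (dx * dy > 0.0) conc += 1.0;
      else disc += 1.0;
    }
  }
  return NumericVector::create(_["concordant"] = conc, _["discordant"] = disc,
                               _["tie_y"] = tie_y, _["tie_x"] = tie_x);
}
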