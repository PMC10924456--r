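#include <Rcpp.h>
using namespace Rcpp;

// Sample an order-1 Markov path over a 4-letter alphabet. The uniforms are
// drawn in R so the path is fully reproducible from R's RNG seed.
// cumP: 4 x 4 row-cumulative transition matrix; init: 1-based start state;
// u: one uniform per subsequent step. Returns 1-based states including init.
// [[Rcpp::export]]
IntegerVector markov_path(NumericMatrix cumP, int init, NumericVector u) {
  R_xlen_t n = u.size();
  IntegerVector out(n + 1);
  int s = init - 1;
  out[0] = init;
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = u[t];
    int k = 0;
    while (k < 3 && x > cumP(s, k)) ++k;
    out[t + 1] = k + 1;
    s = k;
  }
  return out;
}
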