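#include <Rcpp.h>
using namespace Rcpp;

// Sample a first-order Markov chain over the 4-letter DNA alphabet.
// trans is a 4x4 row-stochastic matrix (rows = current base A,C,G,T),
// init the initial base distribution. Uses R's RNG, so draws are
// reproducible under set.seed(). Returns integer codes 0..3.
// [[Rcpp::export(name = ".markov_sample_codes")]]
IntegerVector markov_sample_codes(int n, NumericMatrix trans,
                                  NumericVector init) {
  if (trans.nrow() != 4 || trans.ncol() != 4 || init.size() != 4)
    stop("transition matrix must be 4x4 with a length-4 initial distribution");
  IntegerVector out(n);
  if (n == 0) return out;

  // row-wise cumulative probabilities
  double cum[4][4];
  for (int r = 0; r < 4; ++r) {
    double acc = 0.0;
    for (int c = 0; c < 4; ++c) {
      acc += trans(r, c);
      cum[r][c] = acc;
    }
    if (cum[r][3] <= 0) stop("transition row sums to zero");
    for (int c = 0; c < 4; ++c) cum[r][c] /= cum[r][3];
  }
  double cini[4];
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) { acc += init[c]; cini[c] = acc; }
  for (int c = 0; c < 4; ++c) cini[c] /= acc;

  double u = unif_rand();
  int state = 0;
  while (state < 3 && u > cini[state]) ++state;
  out[0] = state;
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    int s = 0;
    while (s < 3 && u > cum[state][s]) ++s;
    state = s;
    out[i] = state;
  }
  return out;
}
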