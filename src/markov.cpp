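// Sequential samplers used by the synthetic cohort generator.  Both draw
// from R's RNG stream so cohort generation is reproducible under set.seed.

#include <Rcpp.h>
using namespace Rcpp;

// Sample a discrete-state Markov chain of length n.  `init` is the initial
// state distribution, `trans` the row-stochastic transition matrix.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector markov_chain_cpp(int n, NumericVector init,
                               NumericMatrix trans) {
  int k = init.size();
  IntegerVector out(n);
  if (n == 0) return out;
  double u = unif_rand(), acc = 0.0;
  int s = k - 1;
  for (int j = 0; j < k; ++j) {
    acc += init[j];
    if (u <= acc) { s = j; break; }
  }
  out[0] = s + 1;
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    acc = 0.0;
    int nxt = k - 1;
    for (int j = 0; j < k; ++j) {
      acc += trans(s, j);
      if (u <= acc) { nxt = j; break; }
    }
    s = nxt;
    out[i] = s + 1;
  }
  return out;
}
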