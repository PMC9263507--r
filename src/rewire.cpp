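#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving double-edge swap kernel. `edges` holds 0-based
// endpoint pairs (i < j) of the present edges; `w` is the full weight
// matrix, modified in place together with `edges`. Uses R's RNG stream
// so set.seed() in the caller makes the walk reproducible.
// [[Rcpp::export]]
List rewire_swaps(IntegerMatrix edges, NumericMatrix w, int target,
                  int max_attempts) {
  RNGScope scope;
  int m = edges.nrow();
  int done = 0, attempts = 0;
  while (done < target && attempts < max_attempts) {
    attempts++;
    int p1 = (int)(unif_rand() * m); if (p1 >= m) p1 = m - 1;
    int p2 = (int)(unif_rand() * m); if (p2 >= m) p2 = m - 1;
    if (p1 == p2) continue;
    int a = edges(p1, 0), b = edges(p1, 1);
    int c = edges(p2, 0), d = edges(p2, 1);
    if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
    if (a == c || a == d || b == c || b == d) continue;
    if (w(a, d) > 0 || w(c, b) > 0) continue;
    double w1 = w(a, b), w2 = w(c, d);
    w(a, b) = 0; w(b, a) = 0; w(c, d) = 0; w(d, c) = 0;
    w(a, d) = w1; w(d, a) = w1; w(c, b) = w2; w(b, c) = w2;
    edges(p1, 0) = a < d ? a : d; edges(p1, 1) = a < d ? d : a;
    edges(p2, 0) = c < b ? c : b; edges(p2, 1) = c < b ? b : c;
    done++;
  }
  return List::create(_["n_swaps"] = done, _["attempts"] = attempts);
}
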