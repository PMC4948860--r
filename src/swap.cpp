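#include <Rcpp.h>
using namespace Rcpp;

// Independent-swap randomization of an islands x species abundance matrix.
// Repeatedly picks a random 2x2 submatrix; when it is a checkerboard
// (diagonal occupied, off-diagonal empty, or vice versa) the two abundance
// values are moved within their species columns to the opposite islands.
// This preserves per-species occurrence frequency, per-island richness and
// per-species total abundance exactly. Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_independent_swap(IntegerMatrix m, int n_iter) {
  IntegerMatrix x = clone(m);
  int nr = x.nrow(), nc = x.ncol();
  if (nr < 2 || nc < 2) return x;
  for (int it = 0; it < n_iter; ++it) {
    int i = (int)(unif_rand() * nr);
    int j = (int)(unif_rand() * nr);
    int a = (int)(unif_rand() * nc);
    int b = (int)(unif_rand() * nc);
    if (i == j || a == b) continue;
    int xia = x(i, a), xib = x(i, b), xja = x(j, a), xjb = x(j, b);
    if (xia > 0 && xjb > 0 && xib == 0 && xja == 0) {
      x(j, a) = xia; x(i, a) = 0;
      x(i, b) = xjb; x(j, b) = 0;
    } else if (xib > 0 && xja > 0 && xia == 0 && xjb == 0) {
      x(i, a) = xja; x(j, a) = 0;
      x(j, b) = xib; x(i, b) = 0;
    }
  }
  return x;
}
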