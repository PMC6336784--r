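#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard-swap Markov chain over binary matrices with fixed row and
// column sums.  Each step proposes a uniformly chosen pair of rows and pair
// of columns; if the 2x2 submatrix is a checkerboard (10/01 or 01/10) it is
// flipped, which preserves both margins, otherwise the chain stays put.
// The proposal is symmetric and the stay-in-place moves make the chain
// aperiodic, so the stationary distribution is uniform over the family of
// matrices with the observed margins.  Uses R's RNG, so draws are
// reproducible under set.seed().
//
// Returns n_samples rows, each a flattened (column-major) matrix state,
// taken every `thin` steps after `burn` burn-in steps from the initial
// state m0.
// [[Rcpp::export(rng = false)]]
IntegerMatrix swap_chain(IntegerMatrix m0, int n_samples, int burn,
                         int thin) {
  GetRNGstate();
  IntegerMatrix m = clone(m0);
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(n_samples, nr * nc);
  if (n_samples == 0) { PutRNGstate(); return out; }
  long long total = static_cast<long long>(burn) +
    static_cast<long long>(n_samples) * thin;
  int s = 0;
  for (long long it = 1; it <= total; ++it) {
    int i1 = static_cast<int>(unif_rand() * nr);
    int i2 = static_cast<int>(unif_rand() * nr);
    int j1 = static_cast<int>(unif_rand() * nc);
    int j2 = static_cast<int>(unif_rand() * nc);
    if (i1 != i2 && j1 != j2) {
      int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
      if (a == d && b == c && a != b) {
        m(i1, j1) = b; m(i1, j2) = a; m(i2, j1) = d; m(i2, j2) = c;
      }
    }
    if (it > burn && (it - burn) % thin == 0) {
      for (int q = 0; q < nr * nc; ++q) out(s, q) = m[q];
      ++s;
      if (s == n_samples) break;
    }
  }
  PutRNGstate();
  return out;
}
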