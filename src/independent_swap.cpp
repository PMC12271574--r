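#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard (independent) swap on a samples-by-taxa abundance matrix.
// A 2x2 submatrix with occupancy [[+,0],[0,+]] or [[0,+],[+,0]] has its
// nonzero entries moved to the opposite diagonal, carrying abundances, so
// row and column occupancy counts are preserved exactly. Performs n_swaps
// successful swaps or stops after max_tries failed attempts (identity when
// no checkerboard exists). Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
NumericMatrix independent_swap_cpp(NumericMatrix mat, int n_swaps,
                                   double tries_per_swap = 100.0) {
  NumericMatrix m = clone(mat);
  const int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2 || n_swaps == 0) return m;
  const double max_tries = tries_per_swap * n_swaps + 1000.0;
  int done = 0;
  double tries = 0;
  while (done < n_swaps && tries < max_tries) {
    ++tries;
    int r1 = static_cast<int>(unif_rand() * nr);
    int r2 = static_cast<int>(unif_rand() * (nr - 1));
    if (r2 >= r1) ++r2;
    int c1 = static_cast<int>(unif_rand() * nc);
    int c2 = static_cast<int>(unif_rand() * (nc - 1));
    if (c2 >= c1) ++c2;
    double a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    if (a > 0 && d > 0 && b == 0 && c == 0) {
      m(r1, c2) = a; m(r2, c1) = d;
      m(r1, c1) = 0; m(r2, c2) = 0;
      ++done;
    } else if (a == 0 && d == 0 && b > 0 && c > 0) {
      m(r1, c1) = b; m(r2, c2) = c;
      m(r1, c2) = 0; m(r2, c1) = 0;
      ++done;
    }
  }
  return m;
}
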