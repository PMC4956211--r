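#include <Rcpp.h>
using namespace Rcpp;

// One synchronous movement step. Each individual moves with its sex's
// probability; movers draw a destination from the cumulative inverse-distance
// distribution of their current cell (cum[, source] column, self weight 0).
// Draws come from R's RNG so results are reproducible under set.seed().
// Updates are simultaneous: individuals do not interact, so order is
// irrelevant, but positions are read before any is written.
// [[Rcpp::export]]
List cpp_step_movement(IntegerVector cell, LogicalVector male,
                       double male_move_prob, double female_move_prob,
                       NumericMatrix cum) {
  const int n = cell.size();
  const int ncells = cum.nrow();
  IntegerVector newcell(n);
  LogicalVector moved(n);

  for (int i = 0; i < n; ++i) {
    const double p = male[i] ? male_move_prob : female_move_prob;
    const bool mv = unif_rand() < p;
    moved[i] = mv;
    if (!mv) {
      newcell[i] = cell[i];
      continue;
    }
    const int src = cell[i] - 1;
    const double u = unif_rand();
    const double* col = &cum(0, src);
    // first index with cumulative mass >= u; the source cell can never be
    // selected because its cumulative value equals its predecessor's
    int lo = 0, hi = ncells - 1;
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      if (col[mid] < u) lo = mid + 1; else hi = mid;
    }
    newcell[i] = lo + 1;
  }
  return List::create(_["cell"] = newcell, _["moved"] = moved);
}
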