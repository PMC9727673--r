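#include <Rcpp.h>
using namespace Rcpp;

// Iterative Zonation-style cell removal.
//
// occ:      features x cells 0/1 occurrence matrix
// w:        feature weights (> 0)
// cost:     per-cell cost (> 0)
// stratum:  0 = free, 1 = locked-in (removed only after all free cells)
// rule:     0 = CAZ (weighted max), 1 = ABF (weighted sum)
// tiebreak: per-cell random keys; among equal-loss cells the smallest wins
//
// Marginal loss of cell i given remaining totals t_j:
//   q_ji = occ(j,i) / t_j
//   CAZ: max_j w_j * q_ji / cost_i     ABF: sum_j w_j * q_ji / cost_i
// Losses are recomputed from scratch for every remaining cell in the
// active stratum at every iteration; at desk scale this exact greedy is
// fast enough and is the cleanest surface for oracle verification.
//
// Returns the removal sequence (1-based cell indices, first removed first).
// [[Rcpp::export]]
IntegerVector greedy_removal_cpp(NumericMatrix occ, NumericVector w,
                                 NumericVector cost, IntegerVector stratum,
                                 int rule, NumericVector tiebreak) {
  const int nf = occ.nrow(), nc = occ.ncol();
  std::vector<double> totals(nf, 0.0);
  for (int j = 0; j < nf; ++j) {
    for (int i = 0; i < nc; ++i) totals[j] += occ(j, i);
  }
  std::vector<bool> remaining(nc, true);
  IntegerVector order(nc);

  for (int s = 0; s <= 1; ++s) {
    int left = 0;
    for (int i = 0; i < nc; ++i) if (remaining[i] && stratum[i] == s) ++left;
    int step = 0;
    for (int i = 0; i < nc; ++i) if (!remaining[i]) ++step;
    while (left > 0) {
      int best = -1;
      double best_loss = 0.0, best_key = 0.0;
      for (int i = 0; i < nc; ++i) {
        if (!remaining[i] || stratum[i] != s) continue;
        double loss;
        if (rule == 0) {
          double mx = 0.0;
          for (int j = 0; j < nf; ++j) {
            if (occ(j, i) > 0 && totals[j] > 0) {
              double v = w[j] * occ(j, i) / totals[j];
              if (v > mx) mx = v;
            }
          }
          loss = mx / cost[i];
        } else {
          long double sum = 0.0;  // match R's long-double accumulation
          for (int j = 0; j < nf; ++j) {
            if (occ(j, i) > 0 && totals[j] > 0)
              sum += w[j] * occ(j, i) / totals[j];
          }
          loss = (double)(sum) / cost[i];
        }
        if (best < 0 || loss < best_loss ||
            (loss == best_loss && tiebreak[i] < best_key)) {
          best = i;
          best_loss = loss;
          best_key = tiebreak[i];
        }
      }
      remaining[best] = false;
      for (int j = 0; j < nf; ++j) totals[j] -= occ(j, best);
      order[step++] = best + 1;
      --left;
    }
  }
  return order;
}
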