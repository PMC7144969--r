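#include <Rcpp.h>
using namespace Rcpp;

// Harrell's concordance for right-censored data.
//
// Pair convention: observation i can serve as reference if it has an event
// and either t_i < t_j, or t_i == t_j with j censored. Tied event times
// (both events) are incomparable, as are pairs where neither can be the
// reference. Tied risks receive half credit.
//
// Returns per-pair totals plus per-observation sums of concordance credit
// and comparable-pair counts, from which all leave-one-out concordance
// values follow in O(n) (each pair contributes to exactly two observations).

// [[Rcpp::export]]
List concordance_counts(NumericVector time, LogicalVector event,
                        NumericVector risk) {
  const int n = time.size();
  double conc = 0.0, comp = 0.0;
  NumericVector conc_i(n), comp_i(n);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int ref = -1, oth = -1;
      if (time[i] < time[j]) {
        if (event[i]) { ref = i; oth = j; }
      } else if (time[j] < time[i]) {
        if (event[j]) { ref = j; oth = i; }
      } else { // tied times: comparable only if exactly one event
        if (event[i] && !event[j]) { ref = i; oth = j; }
        else if (event[j] && !event[i]) { ref = j; oth = i; }
      }
      if (ref < 0) continue;
      double credit = risk[ref] > risk[oth] ? 1.0 :
                      (risk[ref] == risk[oth] ? 0.5 : 0.0);
      conc += credit; comp += 1.0;
      conc_i[i] += credit; comp_i[i] += 1.0;
      conc_i[j] += credit; comp_i[j] += 1.0;
    }
  }
  return List::create(_["concordant"] = conc, _["comparable"] = comp,
                      _["concordant_by_obs"] = conc_i,
                      _["comparable_by_obs"] = comp_i);
}
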