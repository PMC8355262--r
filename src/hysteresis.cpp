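#include <Rcpp.h>
using namespace Rcpp;

// Assign each sample to a conductance level with hysteresis: starting from
// the level nearest the first sample, a switch from the current level to a
// candidate level only happens when the sample has crossed the midpoint
// between the two level currents by more than `hysteresis * gap` on the
// candidate's side. Suppresses chatter at level midpoints. Levels must be
// sorted by current ascending; returns 1-based level indices.
// [[Rcpp::export]]
IntegerVector hysteresis_assign(NumericVector x, NumericVector levels,
                                double hysteresis) {
  const int n = x.size(), m = levels.size();
  IntegerVector out(n);
  if (m == 1) {
    std::fill(out.begin(), out.end(), 1);
    return out;
  }
  // nearest level to first sample
  int cur = 0;
  double best = std::abs(x[0] - levels[0]);
  for (int k = 1; k < m; ++k) {
    double d = std::abs(x[0] - levels[k]);
    if (d < best) { best = d; cur = k; }
  }
  for (int i = 0; i < n; ++i) {
    // nearest level to this sample
    int cand = 0;
    double bd = std::abs(x[i] - levels[0]);
    for (int k = 1; k < m; ++k) {
      double d = std::abs(x[i] - levels[k]);
      if (d < bd) { bd = d; cand = k; }
    }
    if (cand != cur) {
      double gap = std::abs(levels[cand] - levels[cur]);
      double mid = 0.5 * (levels[cand] + levels[cur]);
      double excursion = (levels[cand] > levels[cur]) ? (x[i] - mid)
                                                      : (mid - x[i]);
      if (excursion > hysteresis * gap) cur = cand;
    }
    out[i] = cur + 1;
  }
  return out;
}
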