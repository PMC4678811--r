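#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact minimization of  sum_seg RSS(seg) + (#changepoints) * penalty
// over all segmentations with segments of length >= min_size, by optimal
// partitioning with PELT pruning (valid here: the mean-change RSS cost is
// additive and satisfies the pruning inequality with K = 0).
//
// Returns the 0-based indices of the LAST point of each non-final segment;
// the R wrapper converts to "first frame of the new segment", 1-based.

// [[Rcpp::export]]
IntegerVector pelt_mean_cpp(NumericVector x, double penalty, int min_size) {
  const int n = x.size();
  if (n < 2 * min_size) return IntegerVector(0);

  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    Q[i + 1] = Q[i] + x[i] * x[i];
  }
  // RSS of the segment covering points s+1..t (1-based cumulative indices)
  auto cost = [&](int s, int t) -> double {
    const double sum = S[t] - S[s];
    const int m = t - s;
    return (Q[t] - Q[s]) - sum * sum / m;
  };

  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> prev(n + 1, 0);
  F[0] = -penalty;

  std::vector<int> cand;
  cand.reserve(n + 1);
  cand.push_back(0);
  std::vector<double> fc(n + 1);  // F[s] + cost(s, t) for current t
  for (int t = min_size; t <= n; ++t) {
    double best = R_PosInf;
    int argbest = 0;
    for (int s : cand) {
      if (t - s < min_size) { fc[s] = -R_PosInf; continue; }  // not yet evaluable: keep
      const double v = F[s] + cost(s, t);
      fc[s] = v;
      if (v + penalty < best) { best = v + penalty; argbest = s; }
    }
    F[t] = best;
    prev[t] = argbest;
    size_t j = 0;
    for (int s : cand) {
      if (fc[s] <= F[t]) cand[j++] = s;  // PELT prune (K = 0)
    }
    cand.resize(j);
    cand.push_back(t);  // becomes evaluable once t' - t >= min_size
  }

  std::vector<int> cps;
  for (int t = prev[n]; t > 0; t = prev[t]) cps.push_back(t);
  std::reverse(cps.begin(), cps.end());
  IntegerVector out(cps.size());
  for (size_t i = 0; i < cps.size(); ++i) out[i] = cps[i];  // last idx of seg, 1-based
  return out;
}
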