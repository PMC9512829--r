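#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Penalized exact least-squares segmentation (PELT) for a change in mean.
// Cost of a segment is its residual sum of squares; each changepoint adds
// `beta`. RSS cost satisfies the pruning condition with K = 0, so pruning
// keeps the search exact. Returns 1-based indices of the last bin of every
// segment except the final one.
// [[Rcpp::export]]
IntegerVector pelt_mean(NumericVector x, double beta) {
  const int n = x.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> cs(n + 1, 0.0), ss(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    ss[i + 1] = ss[i] + x[i] * x[i];
  }
  std::vector<double> F(n + 1, 0.0);
  std::vector<int> prev(n + 1, 0);
  F[0] = -beta;
  std::vector<int> cand;
  cand.reserve(64);
  cand.push_back(0);
  std::vector<int> keep;
  keep.reserve(64);
  for (int t = 1; t <= n; ++t) {
    double best = R_PosInf;
    int arg = 0;
    for (size_t k = 0; k < cand.size(); ++k) {
      const int s = cand[k];
      const double d = cs[t] - cs[s];
      const double cost = ss[t] - ss[s] - d * d / (t - s);
      const double v = F[s] + cost + beta;
      if (v < best) {
        best = v;
        arg = s;
      }
    }
    F[t] = best;
    prev[t] = arg;
    keep.clear();
    for (size_t k = 0; k < cand.size(); ++k) {
      const int s = cand[k];
      const double d = cs[t] - cs[s];
      const double cost = ss[t] - ss[s] - d * d / (t - s);
      if (F[s] + cost <= F[t]) keep.push_back(s);
    }
    keep.push_back(t);
    cand = keep;
  }
  std::vector<int> cps;
  for (int t = n; t > 0; t = prev[t]) {
    if (prev[t] > 0) cps.push_back(prev[t]);
  }
  std::sort(cps.begin(), cps.end());
  return wrap(cps);
}
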