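#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Functional-pruning optimal partitioning (FPOP) for a change in mean with
// RSS segment cost and penalty `beta`. Computes the same exact optimum as
// pelt_mean() but prunes candidates functionally: each candidate carries the
// set of segment-mean values for which it can still be optimal; comparisons
// between candidates are invariant as data accrue (every cost gains the same
// (x_t - mu)^2 term), so a candidate dominated everywhere can never return.
// Returns 1-based indices of the last bin of every segment except the final
// one.

namespace {

struct Interval {
  double a, b;
};

struct Cand {
  int s;                       // last changepoint position (0-based count)
  std::vector<Interval> ivs;   // mean values where s may still be optimal
};

// intersect a union of intervals with [a, b]
static void intersect(std::vector<Interval>& ivs, double a, double b) {
  std::vector<Interval> out;
  out.reserve(ivs.size());
  for (const Interval& iv : ivs) {
    const double lo = std::max(iv.a, a), hi = std::min(iv.b, b);
    if (lo < hi) out.push_back({lo, hi});
  }
  ivs.swap(out);
}

}  // namespace

// [[Rcpp::export]]
IntegerVector fpop_mean(NumericVector x, double beta) {
  const int n = x.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> cs(n + 1, 0.0), ss(n + 1, 0.0);
  double lo = x[0], hi = x[0];
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    ss[i + 1] = ss[i] + x[i] * x[i];
    lo = std::min(lo, x[i]);
    hi = std::max(hi, x[i]);
  }
  lo -= 1.0;
  hi += 1.0;
  std::vector<double> F(n + 1, 0.0);
  std::vector<int> prev(n + 1, 0);
  F[0] = -beta;
  std::vector<Cand> cands;
  cands.push_back({0, {{lo, hi}}});
  std::vector<Interval> occupied;
  for (int t = 1; t <= n; ++t) {
    // minimize each candidate's quadratic over its interval set
    double best = R_PosInf;
    int arg = 0;
    for (const Cand& c : cands) {
      const int m = t - c.s;
      const double S = cs[t] - cs[c.s];
      const double SS = ss[t] - ss[c.s];
      const double A = F[c.s] + beta;
      const double mustar = S / m;
      double v = R_PosInf;
      for (const Interval& iv : c.ivs) {
        double mu = std::min(std::max(mustar, iv.a), iv.b);
        double q = A + SS - 2.0 * mu * S + m * mu * mu;
        v = std::min(v, q);
      }
      if (v < best) {
        best = v;
        arg = c.s;
      }
    }
    F[t] = best;
    prev[t] = arg;
    if (t == n) break;
    // functional pruning: keep each candidate only where its cost stays
    // below the constant F[t] + beta a new segment would start from
    const double cthr = F[t] + beta;
    occupied.clear();
    std::vector<Cand> kept;
    kept.reserve(cands.size() + 1);
    for (Cand& c : cands) {
      const int m = t - c.s;
      const double S = cs[t] - cs[c.s];
      const double SS = ss[t] - ss[c.s];
      const double A = F[c.s] + beta;
      // solve m mu^2 - 2 S mu + (A + SS - cthr) < 0
      const double disc = S * S - m * (A + SS - cthr);
      if (disc <= 0) continue;  // dominated everywhere
      const double root = std::sqrt(disc);
      const double r1 = (S - root) / m, r2 = (S + root) / m;
      intersect(c.ivs, r1, r2);
      if (c.ivs.empty()) continue;
      for (const Interval& iv : c.ivs) occupied.push_back(iv);
      kept.push_back(std::move(c));
    }
    // the new candidate owns the complement of what is still occupied
    std::sort(occupied.begin(), occupied.end(),
              [](const Interval& u, const Interval& v) { return u.a < v.a; });
    std::vector<Interval> free_ivs;
    double cursor = lo;
    for (const Interval& iv : occupied) {
      if (iv.a > cursor) free_ivs.push_back({cursor, iv.a});
      cursor = std::max(cursor, iv.b);
    }
    if (cursor < hi) free_ivs.push_back({cursor, hi});
    if (!free_ivs.empty()) kept.push_back({t, std::move(free_ivs)});
    cands.swap(kept);
  }
  std::vector<int> cps;
  for (int t = n; t > 0; t = prev[t]) {
    if (prev[t] > 0) cps.push_back(prev[t]);
  }
  std::sort(cps.begin(), cps.end());
  return wrap(cps);
}
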