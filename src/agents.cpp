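#include <Rcpp.h>
using namespace Rcpp;

// Matching-law allocation for a focal agent holding help `v` while every
// other agent j keeps its lagged help: r = sum_j b_j * w_v / pool_j with
// pool_j = sum_{l != j} w_l (focal agent's weight replaced by w_v).
// A source whose pool has zero weight splits its help equally.
static double payoff_focal(int i, double v, const NumericVector& b,
                           const NumericVector& w, double sw, double k,
                           double z, double m, double x, int n) {
  double wv = std::pow(v + k, z); // pow(0, 0) == 1: z = 0 is an equal split
  double r = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double bj = b[j];
    if (bj == 0.0) continue;
    double pool = sw - w[j] - w[i] + wv;
    if (pool > 0.0)
      r += bj * wv / pool;
    else
      r += bj / (n - 1);
  }
  return m * r / (m * x + r) - v;
}

// One synchronous step: each agent evaluates one candidate (current help
// plus dirs[i], clamped at zero) against all other agents' lagged help and
// adopts it only on strict improvement.
// [[Rcpp::export(name = ".step_agents_kernel")]]
NumericVector step_agents_kernel(NumericVector h, NumericVector h_prev,
                                 double k, double z, double m, double x,
                                 NumericVector dirs) {
  int n = h.size();
  NumericVector b(n), w(n), out(n);
  double sw = 0.0;
  for (int j = 0; j < n; ++j) {
    b[j] = h_prev[j] + k;
    w[j] = std::pow(b[j], z);
    sw += w[j];
  }
  for (int i = 0; i < n; ++i) {
    double cur = payoff_focal(i, h[i], b, w, sw, k, z, m, x, n);
    double cand = h[i] + dirs[i];
    if (cand < 0.0) cand = 0.0;
    out[i] = h[i];
    if (cand != h[i]) {
      double Wc = payoff_focal(i, cand, b, w, sw, k, z, m, x, n);
      if (Wc > cur) out[i] = cand;
    }
  }
  return out;
}

// Per-agent payoffs of the current population against itself (used for
// summaries along a run without paying the R-level allocation cost).
// [[Rcpp::export(name = ".agent_payoffs_kernel")]]
NumericVector agent_payoffs_kernel(NumericVector h, double k, double z,
                                   double m, double x) {
  int n = h.size();
  NumericVector b(n), w(n), out(n);
  double sw = 0.0;
  for (int j = 0; j < n; ++j) {
    b[j] = h[j] + k;
    w[j] = std::pow(b[j], z);
    sw += w[j];
  }
  for (int i = 0; i < n; ++i)
    out[i] = payoff_focal(i, h[i], b, w, sw, k, z, m, x, n);
  return out;
}
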