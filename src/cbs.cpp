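#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-sample pooled-variance t statistic between the arc (i, j] and its
// complement on the circularly joined segment. S and Q hold cumulative sums
// of the values and squared values (S[0] = Q[0] = 0). Returns |t|; +Inf when
// both pieces are internally constant but their means differ.
static double arc_stat(const std::vector<double> &S, const std::vector<double> &Q,
                       int n, int i, int j) {
  const int n1 = j - i, n2 = n - n1;
  const double s1 = S[j] - S[i], q1 = Q[j] - Q[i];
  const double s2 = S[n] - s1, q2 = Q[n] - q1;
  const double m1 = s1 / n1, m2 = s2 / n2;
  double ss = (q1 - n1 * m1 * m1) + (q2 - n2 * m2 * m2);
  if (ss < 0.0) ss = 0.0;
  const double d = std::fabs(m1 - m2);
  if (n <= 2) return 0.0;
  const double denom = (ss / (n - 2)) * (1.0 / n1 + 1.0 / n2);
  if (denom < 1e-30) return (d > 1e-12) ? R_PosInf : 0.0;
  return d / std::sqrt(denom);
}

static void cumsums(const std::vector<double> &x, std::vector<double> &S,
                    std::vector<double> &Q) {
  const int n = (int)x.size();
  S.assign(n + 1, 0.0);
  Q.assign(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    Q[k + 1] = Q[k] + x[k] * x[k];
  }
}

// Exhaustive scan over admissible arcs (i, j], 0 <= i < j <= n, excluding the
// full segment; admissible iff both arc and complement have >= min_width
// values. Ties break toward the smallest i, then smallest j.
// [[Rcpp::export]]
List cbs_best_arc_cpp(NumericVector x, int min_width) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end()), S, Q;
  cumsums(v, S, Q);
  double best = -1.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      if (i == 0 && j == n) continue;
      const int n1 = j - i;
      if (n1 < min_width || n - n1 < min_width) continue;
      const double t = arc_stat(S, Q, n, i, j);
      if (t > best) {
        best = t;
        bi = i;
        bj = j;
      }
    }
  }
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = best);
}

// Permutation test for the maximal arc statistic. Uses R's RNG (seed set by
// the caller). Stops early once the exceedance count makes p >= alpha
// inevitable. p estimated as (exceed + 1) / (done + 1).
// [[Rcpp::export]]
List cbs_perm_test_cpp(NumericVector x, double t_obs, int min_width, int n_perm,
                       double alpha) {
  const int n = x.size();
  std::vector<double> y(x.begin(), x.end()), S, Q;
  const int max_exceed = (int)std::ceil(alpha * (n_perm + 1));
  int exceed = 0, done = 0;
  RNGScope scope;
  for (int b = 0; b < n_perm; ++b) {
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(y[k], y[idx]);
    }
    cumsums(y, S, Q);
    bool hit = false;
    for (int i = 0; i < n && !hit; ++i) {
      for (int j = i + 1; j <= n; ++j) {
        if (i == 0 && j == n) continue;
        const int n1 = j - i;
        if (n1 < min_width || n - n1 < min_width) continue;
        if (arc_stat(S, Q, n, i, j) >= t_obs) {
          hit = true;
          break;
        }
      }
    }
    if (hit) ++exceed;
    done = b + 1;
    if (exceed >= max_exceed) break;
  }
  const double p = (exceed + 1.0) / (done + 1.0);
  return List::create(_["p"] = p, _["exceed"] = exceed, _["n_done"] = done);
}
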