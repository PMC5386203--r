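#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TWOPI = 2.0 * M_PI;

static inline double reduce_angle(double a) {
  double r = a - TWOPI * std::floor(a / TWOPI);
  if (r < 0.0) r += TWOPI;
  if (r >= TWOPI) r = 0.0;
  return r;
}

// Half-width of the angular window around an existing node at radius rs such
// that a candidate at radius rt lies within hyperbolic distance rt of it.
// approx mode: rs + rt + 2 ln(dtheta/2) <= rt  <=>  dtheta <= 2 exp(-rs/2).
// exact mode:  cosh d = cosh rs cosh rt - sinh rs sinh rt cos dtheta <= cosh rt
//              <=> cos dtheta >= cosh rt (cosh rs - 1) / (sinh rs sinh rt).
static inline double disk_halfwidth(double rs, double rt, bool exact) {
  if (!exact) {
    double hw = 2.0 * std::exp(-rs / 2.0);
    return (hw > M_PI) ? M_PI : hw;
  }
  if (rs <= 0.0 || rt <= 0.0) return M_PI;  // origin: d = |rt - rs| <= rt
  double c = std::cosh(rt) * (std::cosh(rs) - 1.0) /
             (std::sinh(rs) * std::sinh(rt));
  if (c >= 1.0) return 0.0;
  if (c <= -1.0) return M_PI;
  return std::acos(c);
}

// Exact hyperbolic distance (curvature -1), stable formulation:
// cosh x = cosh(r1 - r2) + 2 sinh r1 sinh r2 sin^2(dtheta / 2)
static inline double hyp_exact(double r1, double r2, double dtheta) {
  if (dtheta < 1e-9) return std::fabs(r1 - r2);
  double s2 = std::sin(dtheta / 2.0);
  double arg = std::cosh(r1 - r2) + 2.0 * std::sinh(r1) * std::sinh(r2) * s2 * s2;
  if (arg < 1.0) arg = 1.0;
  return std::acosh(arg);
}

// Range-count increment: candidates (sorted angles sa) falling in the circular
// arc [center - hw, center + hw] get +1 via a difference array over sorted order.
static inline void add_arc(const std::vector<double>& sa, std::vector<int>& diff,
                           double center, double hw) {
  int M = (int)sa.size();
  if (hw >= M_PI) { diff[0] += 1; diff[M] -= 1; return; }
  double lo = reduce_angle(center - hw);
  double hi = reduce_angle(center + hw);
  if (lo <= hi) {
    int i1 = (int)(std::lower_bound(sa.begin(), sa.end(), lo) - sa.begin());
    int i2 = (int)(std::upper_bound(sa.begin(), sa.end(), hi) - sa.begin());
    diff[i1] += 1; diff[i2] -= 1;
  } else {  // arc wraps through 0
    int i2 = (int)(std::upper_bound(sa.begin(), sa.end(), hi) - sa.begin());
    diff[0] += 1; diff[i2] -= 1;
    int i1 = (int)(std::lower_bound(sa.begin(), sa.end(), lo) - sa.begin());
    diff[i1] += 1; diff[M] -= 1;
  }
}

// Grow a GPA network. Per node t: draw t candidate angles, then one selection
// variate (fixed RNG consumption order); attractiveness of every candidate by
// sorted-range counting; link to the m hyperbolically closest existing nodes
// (ties broken by smaller birth time). Returns angles (birth order), edge
// matrix (1-based node ids), and the chosen candidate's attractiveness.
// [[Rcpp::export]]
List gpa_grow(int n, int m, double beta, NumericVector lambda, bool exact) {
  NumericVector angles(n);
  IntegerVector chosenA(n);
  long n_edges = (n >= m) ? (long)m * (m - 1) / 2 + (long)m * (n - m)
                          : (long)n * (n - 1) / 2;
  IntegerMatrix edges((int)n_edges, 2);
  int e = 0;

  std::vector<double> cand, sc, hwv, radii;
  std::vector<int> ord, diff, counts;

  for (int t = 1; t <= n; ++t) {
    if (t % 512 == 0) Rcpp::checkUserInterrupt();
    double rt = 2.0 * std::log((double)t);

    // radii of existing nodes updated to time t, and their disk half-widths
    radii.resize(t - 1);
    hwv.resize(t - 1);
    for (int s = 1; s < t; ++s) {
      double rs = beta * 2.0 * std::log((double)s) + (1.0 - beta) * rt;
      radii[s - 1] = rs;
      hwv[s - 1] = disk_halfwidth(rs, rt, exact);
    }

    // step 1(a): t uniform candidate positions
    cand.resize(t);
    for (int i = 0; i < t; ++i) cand[i] = unif_rand() * TWOPI;
    double u = unif_rand();  // selection variate, always consumed

    // step 1(b): attractiveness of each candidate
    ord.resize(t);
    std::iota(ord.begin(), ord.end(), 0);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return cand[a] < cand[b]; });
    sc.resize(t);
    for (int i = 0; i < t; ++i) sc[i] = cand[ord[i]];
    diff.assign(t + 1, 0);
    for (int s = 0; s < t - 1; ++s) add_arc(sc, diff, angles[s], hwv[s]);
    counts.assign(t, 0);
    int acc = 0;
    for (int i = 0; i < t; ++i) { acc += diff[i]; counts[ord[i]] = acc; }

    // step 1(c): select candidate i with probability (A_i + Lambda) / sum
    double lam = lambda[t - 1];
    double W = 0.0;
    for (int i = 0; i < t; ++i) W += counts[i] + lam;
    int pick;
    if (W <= 0.0) {  // degenerate all-zero weights: uniform among candidates
      pick = (int)std::floor(u * t);
      if (pick >= t) pick = t - 1;
    } else {
      pick = t - 1;
      double target = u * W, cum = 0.0;
      for (int i = 0; i < t; ++i) {
        cum += counts[i] + lam;
        if (target <= cum) { pick = i; break; }
      }
    }
    angles[t - 1] = cand[pick];
    chosenA[t - 1] = counts[pick];

    // step 3: connect to the K = min(m, t-1) hyperbolically closest nodes
    int K = std::min(m, t - 1);
    if (K > 0) {
      std::vector<std::pair<double, int> > key(t - 1);
      for (int s = 1; s < t; ++s) {
        double d = std::fabs(angles[s - 1] - angles[t - 1]);
        if (d > M_PI) d = TWOPI - d;
        double k;
        if (exact) {
          k = hyp_exact(radii[s - 1], rt, d);
        } else {
          // rt additive constant dropped; dtheta = 0 -> -Inf (closest)
          k = radii[s - 1] + 2.0 * std::log(d / 2.0);
        }
        key[s - 1] = std::make_pair(k, s);
      }
      std::partial_sort(key.begin(), key.begin() + K, key.end());
      for (int k = 0; k < K; ++k) {
        edges(e, 0) = key[k].second;
        edges(e, 1) = t;
        ++e;
      }
    }
  }
  return List::create(_["angles"] = angles, _["edges"] = edges,
                      _["chosenA"] = chosenA);
}

// Monte-Carlo sample bank for the Lambda likelihood: for t = 2..n0 compute the
// observed attractiveness A_t(theta_t) and, per MC path j, the sum over the
// truncated candidate path of A_t(phi_i^(j)), i = 1..t-1. cand is N x n0.
// [[Rcpp::export]]
List gpa_mc_bank(NumericVector theta, double beta, bool exact,
                 NumericMatrix cand) {
  int n0 = theta.size(), N = cand.nrow();
  IntegerVector obsA(n0 - 1);
  NumericMatrix sumA(n0 - 1, N);

  std::vector<double> vals, sa;
  std::vector<int> ord, diff, counts;

  for (int t = 2; t <= n0; ++t) {
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
    double rt = 2.0 * std::log((double)t);
    int Tm1 = t - 1;
    int M = N * Tm1 + 1;

    vals.resize(M);
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < Tm1; ++i)
        vals[(size_t)j * Tm1 + i] = cand(j, i);
    vals[M - 1] = theta[t - 1];

    ord.resize(M);
    std::iota(ord.begin(), ord.end(), 0);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return vals[a] < vals[b]; });
    sa.resize(M);
    for (int i = 0; i < M; ++i) sa[i] = vals[ord[i]];

    diff.assign(M + 1, 0);
    for (int s = 1; s < t; ++s) {
      double rs = beta * 2.0 * std::log((double)s) + (1.0 - beta) * rt;
      add_arc(sa, diff, theta[s - 1], disk_halfwidth(rs, rt, exact));
    }

    counts.assign(M, 0);
    int acc = 0;
    for (int i = 0; i < M; ++i) { acc += diff[i]; counts[ord[i]] = acc; }

    for (int j = 0; j < N; ++j) {
      double S = 0.0;
      for (int i = 0; i < Tm1; ++i) S += counts[(size_t)j * Tm1 + i];
      sumA(t - 2, j) = S;
    }
    obsA[t - 2] = counts[M - 1];
  }
  return List::create(_["obsA"] = obsA, _["sumA"] = sumA);
}
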