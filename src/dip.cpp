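#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

// Exact Hartigan-Hartigan dip statistic.
//
// dip(x) = min over unimodal cdfs U of sup_t |F_n(t) - U(t)|, where F_n is
// the ECDF. A unimodal U within sup-distance d of F_n exists iff a
// nondecreasing convex-then-concave function threads the corridor
// [F_n - d, F_n + d] (evaluated at the step corners). Threading feasibility
// is decided exactly by propagating, point by point, the reachable frontier
// of (value, entering slope) pairs of convex functions through the corridor
// - a nondecreasing piecewise-linear graph - forward for the convex limb and
// (by reflection) backward for the concave limb, then checking that some
// modal gap joins a feasible convex prefix to a feasible concave suffix
// monotonically. The dip is found by bisection on d; every sample satisfies
// dip >= 1/(2n).

namespace {

struct Sweep {
  std::vector<char> feas; // prefix 1..j threadable by a convex function
  std::vector<double> A;  // minimal achievable value at point j
};

// Forward convex sweep through corridors [lo_i, hi_i] at positions x_i.
// The frontier is a graph (V[k], S[k]) with V strictly increasing and S
// nondecreasing: S_k is the minimal entering slope when the function takes
// value V_k at the current point; between graph points the minimal slope
// interpolates linearly. Advancing by dx maps V -> V + dx * S, values above
// the old top are reachable with slope growing at rate 1/dx, and the graph
// is clipped to the next corridor.
Sweep convex_sweep(const std::vector<double>& x, const std::vector<double>& lo,
                   const std::vector<double>& hi) {
  const size_t n = x.size();
  Sweep out;
  out.feas.assign(n, 0);
  out.A.assign(n, std::numeric_limits<double>::quiet_NaN());
  if (lo[0] > hi[0]) return out;
  std::vector<double> V, S;
  V.reserve(n + 2);
  S.reserve(n + 2);
  V.push_back(lo[0]);
  S.push_back(0.0);
  if (hi[0] > lo[0]) {
    V.push_back(hi[0]);
    S.push_back(0.0);
  }
  out.feas[0] = 1;
  out.A[0] = V.front();
  for (size_t j = 1; j < n; ++j) {
    if (lo[j] > hi[j]) return out;
    const double dx = x[j] - x[j - 1];
    for (size_t k = 0; k < V.size(); ++k) V[k] += dx * S[k];
    const double top =
        dx > 0 ? std::numeric_limits<double>::infinity() : V.back();
    if (lo[j] > top || hi[j] < V.front()) return out;
    // upper clip / extension to hi[j]
    if (hi[j] <= V.back()) {
      size_t k = V.size() - 1;
      while (k > 0 && V[k - 1] >= hi[j]) --k;
      // V[k-1] < hi[j] <= V[k]  (k >= 1 unless hi == V.front())
      double s_at;
      if (k == 0) {
        s_at = S[0];
        V.assign(1, hi[j]);
        S.assign(1, s_at);
      } else {
        s_at = (V[k] > V[k - 1])
                   ? S[k - 1] + (S[k] - S[k - 1]) * (hi[j] - V[k - 1]) /
                                    (V[k] - V[k - 1])
                   : S[k];
        V.resize(k + 1);
        S.resize(k + 1);
        V[k] = hi[j];
        S[k] = s_at;
      }
    } else if (dx > 0) {
      V.push_back(hi[j]);
      S.push_back(S.back() + (hi[j] - V[V.size() - 2]) / dx);
    }
    // lower clip to lo[j]
    if (lo[j] > V.front()) {
      size_t k = 0;
      while (k + 1 < V.size() && V[k + 1] <= lo[j]) ++k;
      // V[k] <= lo[j] < V[k+1]  (or k = last)
      double s_at;
      if (k + 1 == V.size()) {
        s_at = S[k]; // lo == V.back() within tolerance
        V.assign(1, lo[j]);
        S.assign(1, s_at);
      } else {
        s_at = (V[k + 1] > V[k])
                   ? S[k] + (S[k + 1] - S[k]) * (lo[j] - V[k]) /
                                (V[k + 1] - V[k])
                   : S[k + 1];
        std::vector<double> V2(V.begin() + k + 1, V.end());
        std::vector<double> S2(S.begin() + k + 1, S.end());
        V2.insert(V2.begin(), lo[j]);
        S2.insert(S2.begin(), s_at);
        V.swap(V2);
        S.swap(S2);
      }
    }
    out.feas[j] = 1;
    out.A[j] = V.front();
  }
  return out;
}

bool feasible(const std::vector<double>& x, double d) {
  const size_t n = x.size();
  std::vector<double> lo(n), hi(n);
  for (size_t i = 0; i < n; ++i) {
    const double yl = static_cast<double>(i) / n;
    const double yu = static_cast<double>(i + 1) / n;
    lo[i] = std::max(yu - d, 0.0);
    hi[i] = std::min(yl + d, 1.0);
  }
  Sweep fwd = convex_sweep(x, lo, hi);
  if (fwd.feas[n - 1]) return true; // mode beyond the largest point
  // reflected sweep: concave suffixes
  std::vector<double> xr(n), lor(n), hir(n);
  for (size_t i = 0; i < n; ++i) {
    xr[i] = -x[n - 1 - i];
    lor[i] = 1.0 - hi[n - 1 - i];
    hir[i] = 1.0 - lo[n - 1 - i];
  }
  Sweep bwd = convex_sweep(xr, lor, hir);
  if (bwd.feas[n - 1]) return true; // mode below the smallest point
  // join a convex prefix 1..m to a concave suffix m+1..n
  for (size_t m = 1; m < n; ++m) {
    const size_t rb = n - 1 - m; // reflected index of original point m+1
    if (fwd.feas[m - 1] && bwd.feas[rb]) {
      const double B = 1.0 - bwd.A[rb]; // max achievable value at m+1
      if (fwd.A[m - 1] <= B + 1e-14) return true;
    }
  }
  // atom of U at x_1: concave everywhere, upper corridor at x_1 relaxed
  {
    std::vector<double> hi1 = hi;
    hi1[0] = std::min(1.0 / n + d, 1.0); // yu_1 + d
    std::vector<double> lor1(n), hir1(n);
    for (size_t i = 0; i < n; ++i) {
      lor1[i] = 1.0 - hi1[n - 1 - i];
      hir1[i] = 1.0 - lo[n - 1 - i];
    }
    Sweep s = convex_sweep(xr, lor1, hir1);
    if (s.feas[n - 1]) return true;
  }
  // atom of U at x_n: convex everywhere, lower corridor at x_n relaxed
  {
    std::vector<double> lo2 = lo;
    lo2[n - 1] = std::max(static_cast<double>(n - 1) / n - d, 0.0); // yl_n - d
    Sweep s = convex_sweep(x, lo2, hi);
    if (s.feas[n - 1]) return true;
  }
  return false;
}

} // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(Rcpp::NumericVector xs) {
  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());
  const size_t n = x.size();
  if (n == 0) Rcpp::stop("empty sample");
  if (n == 1) return 0.0;
  if (x.front() == x.back()) return 1.0 / (2.0 * n);
  const double emin = 1.0 / n;
  if (feasible(x, emin / 2.0)) return emin / 2.0;
  double elo = emin, ehi = 1.0;
  for (int it = 0; it < 70 && ehi - elo > 1e-14; ++it) {
    const double mid = 0.5 * (elo + ehi);
    if (feasible(x, mid / 2.0)) ehi = mid;
    else elo = mid;
  }
  return ehi / 2.0;
}
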