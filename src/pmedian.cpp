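#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <ctime>
using namespace Rcpp;

// All point/candidate indices at this layer are 0-based positions into the
// distance matrix; R wrappers translate to 1-based instance indices.

// Nearest and second-nearest open facility per destination. `fac` must be
// sorted ascending so that distance ties resolve to the lowest index.
static void nearest_two(const NumericMatrix& d, const std::vector<int>& fac,
                        std::vector<int>& a1, std::vector<double>& d1,
                        std::vector<int>& a2, std::vector<double>& d2) {
  const int n = d.nrow();
  a1.assign(n, -1); a2.assign(n, -1);
  d1.assign(n, R_PosInf); d2.assign(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double b1 = R_PosInf, b2 = R_PosInf; int j1 = -1, j2 = -1;
    for (size_t t = 0; t < fac.size(); ++t) {
      const int f = fac[t];
      const double dd = d(i, f);
      if (dd < b1) { b2 = b1; j2 = j1; b1 = dd; j1 = f; }
      else if (dd < b2) { b2 = dd; j2 = f; }
    }
    a1[i] = j1; d1[i] = b1; a2[i] = j2; d2[i] = b2;
  }
}

static double weighted_cost(const NumericVector& w, const std::vector<double>& d1) {
  double z = 0.0;
  for (size_t i = 0; i < d1.size(); ++i) z += w[i] * d1[i];
  return z;
}

// [[Rcpp::export]]
List cpp_evaluate(NumericMatrix d, NumericVector w, IntegerVector fac0) {
  std::vector<int> fac(fac0.begin(), fac0.end());
  std::sort(fac.begin(), fac.end());
  std::vector<int> a1, a2; std::vector<double> d1, d2;
  nearest_two(d, fac, a1, d1, a2, d2);
  return List::create(_["assign"] = wrap(a1), _["dist"] = wrap(d1),
                      _["objective"] = weighted_cost(w, d1));
}

// Best single swap under nearest/second-nearest bookkeeping.
// delta(j, f) = sum_i w_i (min(d_ij, d1_i) - d1_i)
//             + sum_{i: a1_i = f} w_i (min(d_ij, d2_i) - min(d_ij, d1_i))
// which equals the full re-evaluation of the swapped set exactly.
static void best_swap_scan(const NumericMatrix& d, const NumericVector& w,
                           const std::vector<int>& cand,
                           const std::vector<int>& fac,
                           const std::vector<int>& a1,
                           const std::vector<double>& d1,
                           const std::vector<double>& d2,
                           int& best_in, int& best_out, double& best_delta,
                           long& n_eval) {
  const int n = d.nrow();
  std::vector<char> in_sol(n, 0);
  for (size_t t = 0; t < fac.size(); ++t) in_sol[fac[t]] = 1;
  // position of facility index within sorted fac, for the loss table
  std::vector<int> pos(n, -1);
  for (size_t t = 0; t < fac.size(); ++t) pos[fac[t]] = (int)t;
  best_in = -1; best_out = -1; best_delta = 0.0; n_eval = 0;
  std::vector<double> loss(fac.size());
  for (size_t cj = 0; cj < cand.size(); ++cj) {
    const int j = cand[cj];
    if (in_sol[j]) continue;
    double gain = 0.0;
    std::fill(loss.begin(), loss.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double dij = d(i, j);
      const double m1 = std::min(dij, d1[i]);
      gain += w[i] * (m1 - d1[i]);
      const int f = a1[i];
      loss[pos[f]] += w[i] * (std::min(dij, d2[i]) - m1);
    }
    for (size_t t = 0; t < fac.size(); ++t) {
      const double delta = gain + loss[t];
      ++n_eval;
      if (delta < best_delta) { best_delta = delta; best_in = j; best_out = fac[t]; }
    }
  }
}

// [[Rcpp::export]]
List cpp_best_swap(NumericMatrix d, NumericVector w, IntegerVector cand0,
                   IntegerVector fac0) {
  std::vector<int> cand(cand0.begin(), cand0.end());
  std::vector<int> fac(fac0.begin(), fac0.end());
  std::sort(cand.begin(), cand.end());
  std::sort(fac.begin(), fac.end());
  std::vector<int> a1, a2; std::vector<double> d1, d2;
  nearest_two(d, fac, a1, d1, a2, d2);
  int bi, bo; double bd; long ne;
  best_swap_scan(d, w, cand, fac, a1, d1, d2, bi, bo, bd, ne);
  return List::create(_["enter"] = bi, _["leave"] = bo, _["delta"] = bd,
                      _["swaps_evaluated"] = (double)ne,
                      _["objective"] = weighted_cost(w, d1));
}

// Fast interchange: apply the best-improving swap until none exists.
// [[Rcpp::export]]
List cpp_fast_interchange(NumericMatrix d, NumericVector w, IntegerVector cand0,
                          IntegerVector init0, int max_iter) {
  std::vector<int> cand(cand0.begin(), cand0.end());
  std::vector<int> fac(init0.begin(), init0.end());
  std::sort(cand.begin(), cand.end());
  std::sort(fac.begin(), fac.end());
  std::vector<int> a1, a2; std::vector<double> d1, d2;
  nearest_two(d, fac, a1, d1, a2, d2);
  const double z0 = weighted_cost(w, d1);
  std::vector<double> trace; trace.push_back(z0);
  std::vector<double> swaps;
  int t = 0;
  while (max_iter < 0 || t < max_iter) {
    int bi, bo; double bd; long ne;
    best_swap_scan(d, w, cand, fac, a1, d1, d2, bi, bo, bd, ne);
    swaps.push_back((double)ne);
    const double z = trace.back();
    // improvements below 1e-12 * |Z| treated as zero to guarantee termination
    if (bi < 0 || bd >= -1e-12 * std::max(std::abs(z), 1.0)) break;
    fac.erase(std::lower_bound(fac.begin(), fac.end(), bo));
    fac.insert(std::lower_bound(fac.begin(), fac.end(), bi), bi);
    nearest_two(d, fac, a1, d1, a2, d2);
    trace.push_back(weighted_cost(w, d1));
    ++t;
  }
  return List::create(_["facilities"] = wrap(fac), _["assign"] = wrap(a1),
                      _["objective"] = trace.back(), _["initial_objective"] = z0,
                      _["iterations"] = t, _["z_trace"] = wrap(trace),
                      _["swaps_per_iteration"] = wrap(swaps));
}

// Exhaustive enumeration of all size-p candidate subsets (test oracle).
// First optimum in lexicographic order is kept.
// [[Rcpp::export]]
List cpp_brute_force(NumericMatrix d, NumericVector w, IntegerVector cand0, int p) {
  std::vector<int> cand(cand0.begin(), cand0.end());
  std::sort(cand.begin(), cand.end());
  const int m = (int)cand.size(), n = d.nrow();
  std::vector<int> idx(p);
  for (int t = 0; t < p; ++t) idx[t] = t;
  std::vector<int> best;
  double best_z = R_PosInf;
  for (;;) {
    double z = 0.0;
    for (int i = 0; i < n; ++i) {
      double b = R_PosInf;
      for (int t = 0; t < p; ++t) b = std::min(b, d(i, cand[idx[t]]));
      z += w[i] * b;
      if (z >= best_z) { /* keep summing; subsets are cheap at oracle size */ }
    }
    if (z < best_z) {
      best_z = z;
      best.resize(p);
      for (int t = 0; t < p; ++t) best[t] = cand[idx[t]];
    }
    int t = p - 1;
    while (t >= 0 && idx[t] == m - p + t) --t;
    if (t < 0) break;
    ++idx[t];
    for (int s = t + 1; s < p; ++s) idx[s] = idx[s - 1] + 1;
  }
  return List::create(_["facilities"] = wrap(best), _["objective"] = best_z);
}

struct BnB {
  const NumericMatrix& d;
  const NumericVector& w;
  const std::vector<int>& cand;
  int p, n, m;
  std::vector<double> suf;      // (m+1) x n suffix minima over candidate columns
  std::vector<int> incumbent;
  double inc_z;
  double root_bound;
  double t_limit;               // seconds; < 0 means unlimited
  std::clock_t t0;
  bool timed_out;
  long nodes;

  BnB(const NumericMatrix& d_, const NumericVector& w_,
      const std::vector<int>& cand_, int p_, double tl)
    : d(d_), w(w_), cand(cand_), p(p_), n(d_.nrow()), m((int)cand_.size()),
      inc_z(R_PosInf), t_limit(tl), timed_out(false), nodes(0) {
    suf.assign((size_t)(m + 1) * n, R_PosInf);
    for (int pos = m - 1; pos >= 0; --pos)
      for (int i = 0; i < n; ++i)
        suf[(size_t)pos * n + i] =
          std::min(suf[(size_t)(pos + 1) * n + i], d(i, cand[pos]));
    root_bound = 0.0;
    for (int i = 0; i < n; ++i) root_bound += w[i] * suf[i];
    t0 = std::clock();
  }

  bool expired() {
    if (t_limit < 0) return false;
    return ((double)(std::clock() - t0) / CLOCKS_PER_SEC) > t_limit;
  }

  // Greedy-addition incumbent so that a feasible solution always exists.
  void greedy_start() {
    std::vector<double> bestd(n, R_PosInf);
    std::vector<char> used(m, 0);
    std::vector<int> sol;
    for (int r = 0; r < p; ++r) {
      int arg = -1; double argz = R_PosInf;
      for (int t = 0; t < m; ++t) {
        if (used[t]) continue;
        double z = 0.0;
        for (int i = 0; i < n; ++i)
          z += w[i] * std::min(bestd[i], d(i, cand[t]));
        if (z < argz) { argz = z; arg = t; }
      }
      used[arg] = 1; sol.push_back(cand[arg]);
      for (int i = 0; i < n; ++i)
        bestd[i] = std::min(bestd[i], d(i, cand[arg]));
    }
    std::sort(sol.begin(), sol.end());
    incumbent = sol;
    inc_z = 0.0;
    for (int i = 0; i < n; ++i) inc_z += w[i] * bestd[i];
  }

  void dfs(int pos, int chosen, std::vector<int>& sel, std::vector<double>& bestd) {
    if (timed_out) return;
    if ((++nodes & 2047) == 0 && expired()) { timed_out = true; return; }
    if (chosen == p) {
      double z = 0.0;
      for (int i = 0; i < n; ++i) z += w[i] * bestd[i];
      if (z < inc_z) { inc_z = z; incumbent = sel; }
      return;
    }
    if (m - pos < p - chosen) return;
    double bound = 0.0;
    const double* s = &suf[(size_t)pos * n];
    for (int i = 0; i < n; ++i) bound += w[i] * std::min(bestd[i], s[i]);
    if (bound >= inc_z) return;
    // include cand[pos]
    std::vector<double> nb(n);
    for (int i = 0; i < n; ++i) nb[i] = std::min(bestd[i], d(i, cand[pos]));
    sel.push_back(cand[pos]);
    dfs(pos + 1, chosen + 1, sel, nb);
    sel.pop_back();
    // exclude cand[pos]
    dfs(pos + 1, chosen, sel, bestd);
  }
};

// Exact branch-and-bound for the p-median LIP. Returns the incumbent, a valid
// global lower bound, and whether optimality was proven within the time limit.
// [[Rcpp::export]]
List cpp_branch_bound(NumericMatrix d, NumericVector w, IntegerVector cand0,
                      int p, double time_limit) {
  std::vector<int> cand(cand0.begin(), cand0.end());
  std::sort(cand.begin(), cand.end());
  BnB bb(d, w, cand, p, time_limit);
  bb.greedy_start();
  bool ran = time_limit != 0.0;
  if (ran) {
    std::vector<int> sel; sel.reserve(p);
    std::vector<double> bestd(bb.n, R_PosInf);
    bb.dfs(0, 0, sel, bestd);
  }
  const bool optimal = ran && !bb.timed_out;
  std::sort(bb.incumbent.begin(), bb.incumbent.end());
  return List::create(_["facilities"] = wrap(bb.incumbent),
                      _["objective"] = bb.inc_z,
                      _["bound"] = optimal ? bb.inc_z : bb.root_bound,
                      _["optimal"] = optimal,
                      _["nodes"] = (double)bb.nodes);
}
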