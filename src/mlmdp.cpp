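// Core search for the maximum-likelihood mixture decomposition:
// enumeration of candidate integer interval-count columns restricted by the
// compatible-order constraint, with a convex 1-D (n = 2) or 2-D (n = 3)
// subproblem solved per candidate.
#include <Rcpp.h>
#include <functional>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

constexpr double INF = std::numeric_limits<double>::infinity();

// Minimize f(t) = -sum_g R_g log((1-t) u_g + t v_g) over t in [0, 1].
// f is convex; f' is increasing, so the minimizer is located by a
// safeguarded Newton/bisection root find on f'. Groups with R_g <= 0 are
// inert. Returns t*; *nll_out receives f(t*). Entries of u, v are >= 0.
double segment_minimize(const std::vector<double>& u,
                        const std::vector<double>& v,
                        const std::vector<double>& R,
                        double tol, double* nll_out) {
  const size_t G = u.size();
  bool u_ok = true, v_ok = true;      // all active p positive at t = 0 / 1
  bool degenerate = false;            // some active group with u = v = 0
  for (size_t g = 0; g < G; ++g) {
    if (R[g] <= 0.0) continue;
    if (u[g] <= 0.0) u_ok = false;
    if (v[g] <= 0.0) v_ok = false;
    if (u[g] <= 0.0 && v[g] <= 0.0) degenerate = true;
  }
  if (degenerate) { *nll_out = INF; return 0.0; }

  auto fprime = [&](double t, double* fpp) -> double {
    double fp = 0.0, f2 = 0.0;
    for (size_t g = 0; g < G; ++g) {
      if (R[g] <= 0.0) continue;
      double d = v[g] - u[g];
      double p = u[g] + t * d;
      double q = d / p;
      fp -= R[g] * q;
      f2 += R[g] * q * q;
    }
    if (fpp) *fpp = f2;
    return fp;
  };
  auto fval = [&](double t) -> double {
    double f = 0.0;
    for (size_t g = 0; g < G; ++g) {
      if (R[g] <= 0.0) continue;
      double p = u[g] + t * (v[g] - u[g]);
      if (p <= 0.0) return INF;
      f -= R[g] * std::log(p);
    }
    return f;
  };

  double tstar;
  if (u_ok && fprime(0.0, nullptr) >= 0.0) {
    tstar = 0.0;
  } else if (v_ok && fprime(1.0, nullptr) <= 0.0) {
    tstar = 1.0;
  } else {
    // interior root of f'; invariant f'(lo) < 0 < f'(hi)
    double lo = 0.0, hi = 1.0, t = 0.5;
    for (int it = 0; it < 200 && (hi - lo) > tol; ++it) {
      double f2;
      double fp = fprime(t, &f2);
      if (fp == 0.0) break;
      if (fp < 0.0) lo = t; else hi = t;
      double tn = (f2 > 0.0) ? t - fp / f2 : (lo + hi) / 2.0;
      t = (tn > lo && tn < hi) ? tn : (lo + hi) / 2.0;
    }
    tstar = t;
  }
  *nll_out = fval(tstar);
  return tstar;
}

// Keep all candidates whose objective is within tie_tol of the running best.
template <typename Payload>
struct TieSet {
  double best = INF;
  double tie_tol;
  std::vector<double> nll;
  std::vector<Payload> payload;
  explicit TieSet(double tol) : tie_tol(tol) {}
  void offer(double value, Payload&& p) {
    if (value > best + tie_tol) return;
    if (value < best) {
      best = value;
      // prune entries no longer within tolerance of the new best
      size_t w = 0;
      for (size_t i = 0; i < nll.size(); ++i) {
        if (nll[i] <= best + tie_tol) {
          if (w != i) {  // guard against self-move-assignment
            nll[w] = nll[i];
            payload[w] = std::move(payload[i]);
          }
          ++w;
        }
      }
      nll.resize(w);
      payload.resize(w);
    }
    nll.push_back(value);
    payload.push_back(std::move(p));
  }
};

struct N2Sol {
  std::vector<int> c;   // sorted-position order
  double t;             // internal tumor mixing fraction mu2'
};

struct N3Sol {
  int a, b;             // column indices
  double mu1, mu2, mu3; // internal mixing vector
};

}  // namespace

// Solve the n = 2 problem: enumerate tumor columns c2 in {0..k}^m that have
// compatible (weak-monotone) order with r and respect per-interval bounds,
// and minimize -sum_j r_j log((1-t)/m + t c2_j / ||c2||_1) over t for each.
// r may be real valued (transformed read depths). When order_pruning is
// false every column within bounds is visited (guarded against blow-up).
// [[Rcpp::export]]
List cpp_solve_n2(NumericVector r, IntegerVector lower, IntegerVector upper,
                  int k, double tie_tol, double opt_tol,
                  bool count_only, bool order_pruning) {
  const int m = r.size();
  if (lower.size() != m || upper.size() != m)
    stop("bounds must have one entry per interval");
  for (int j = 0; j < m; ++j) {
    if (lower[j] < 0 || upper[j] > k || lower[j] > upper[j])
      stop("infeasible bounds");
  }
  if (!order_pruning) {
    double sz = 1.0;
    for (int j = 0; j < m; ++j) sz *= (upper[j] - lower[j] + 1);
    if (sz > 2e6) stop("exhaustive (unpruned) enumeration too large");
  }

  // sort interval indices by r ascending; ties share a group
  std::vector<int> ord(m);
  for (int j = 0; j < m; ++j) ord[j] = j;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return r[a] < r[b]; });
  std::vector<bool> newgrp(m, false);
  for (int t = 0; t < m; ++t)
    newgrp[t] = (t == 0) || (r[ord[t]] > r[ord[t - 1]]);

  std::vector<double> rs(m);
  for (int t = 0; t < m; ++t) rs[t] = r[ord[t]];
  double rtot = 0.0;
  for (int t = 0; t < m; ++t) rtot += rs[t];

  std::vector<double> Rv(k + 1, 0.0);   // sum of r over positions at value v
  std::vector<int> val(m, 0);
  long long S = 0;                      // sum of assigned copy values
  double count = 0.0;
  TieSet<N2Sol> ties(tie_tol);

  std::vector<double> u(k + 1), v(k + 1), Rg(k + 1);

  std::function<void(int, int, int)> dfs = [&](int t, int groupFloor,
                                               int maxSoFar) {
    if (t == m) {
      count += 1.0;
      if (count_only) return;
      double nll;
      double topt;
      if (S == 0) {
        // empty tumor genome: p is the uniform normal profile
        topt = 0.0;
        nll = 0.0;
        for (int q = 0; q < m; ++q) nll -= rs[q] * std::log(1.0 / m);
      } else {
        int G = 0;
        for (int x = 0; x <= k; ++x) {
          if (Rv[x] <= 0.0) continue;
          u[G] = 1.0 / m;
          v[G] = static_cast<double>(x) / S;
          Rg[G] = Rv[x];
          ++G;
        }
        std::vector<double> uu(u.begin(), u.begin() + G);
        std::vector<double> vv(v.begin(), v.begin() + G);
        std::vector<double> RR(Rg.begin(), Rg.begin() + G);
        topt = segment_minimize(uu, vv, RR, opt_tol, &nll);
      }
      N2Sol s;
      s.t = topt;
      s.c = val;
      ties.offer(nll, std::move(s));
      return;
    }
    int flo = newgrp[t] ? maxSoFar : groupFloor;
    int j = ord[t];
    int vlo = order_pruning ? std::max(flo, lower[j]) : lower[j];
    int vhi = upper[j];
    for (int x = vlo; x <= vhi; ++x) {
      val[t] = x;
      Rv[x] += rs[t];
      S += x;
      dfs(t + 1, flo, std::max(maxSoFar, x));
      S -= x;
      Rv[x] -= rs[t];
    }
  };
  dfs(0, 0, 0);

  List sols;
  if (!count_only) {
    sols = List(ties.nll.size());
    for (size_t i = 0; i < ties.nll.size(); ++i) {
      IntegerVector c(m);
      for (int t = 0; t < m; ++t) c[ord[t]] = ties.payload[i].c[t];
      sols[i] = List::create(_["c2"] = c,
                             _["mu2_internal"] = ties.payload[i].t,
                             _["nll"] = ties.nll[i]);
    }
  }
  return List::create(_["count"] = count,
                      _["best_nll"] = count_only ? NA_REAL : ties.best,
                      _["solutions"] = sols);
}

// Enumerate the n = 2 candidate columns for small instances (testing aid).
// [[Rcpp::export]]
IntegerMatrix cpp_enumerate_n2(NumericVector r, IntegerVector lower,
                               IntegerVector upper, int k) {
  const int m = r.size();
  std::vector<int> ord(m);
  for (int j = 0; j < m; ++j) ord[j] = j;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return r[a] < r[b]; });
  std::vector<bool> newgrp(m, false);
  for (int t = 0; t < m; ++t)
    newgrp[t] = (t == 0) || (r[ord[t]] > r[ord[t - 1]]);
  for (int j = 0; j < m; ++j)
    if (lower[j] < 0 || upper[j] > k || lower[j] > upper[j])
      stop("infeasible bounds");

  std::vector<std::vector<int>> out;
  std::vector<int> val(m, 0);
  std::function<void(int, int, int)> dfs = [&](int t, int groupFloor,
                                               int maxSoFar) {
    if (t == m) {
      if (out.size() >= 1000000) stop("enumeration too large");
      std::vector<int> c(m);
      for (int q = 0; q < m; ++q) c[ord[q]] = val[q];
      out.push_back(c);
      return;
    }
    int flo = newgrp[t] ? maxSoFar : groupFloor;
    int j = ord[t];
    for (int x = std::max(flo, lower[j]); x <= upper[j]; ++x) {
      val[t] = x;
      dfs(t + 1, flo, std::max(maxSoFar, x));
    }
  };
  dfs(0, 0, 0);
  IntegerMatrix M(out.size(), m);
  for (size_t i = 0; i < out.size(); ++i)
    for (int j = 0; j < m; ++j) M(i, j) = out[i][j];
  return M;
}

// Solve the n = 3 problem over unordered pairs (c2, c3) of tumor columns
// within bounds. A pair is pruned when some (i, j) with r_i < r_j has an
// order inversion in BOTH tumor columns (then no mixture with positive tumor
// mass can have compatible order with r). The convex subproblem over the
// 2-simplex is solved by alternating exact line minimizations in the
// parametrization mu' = ((1-a)(1-b), a, (1-a)b).
// [[Rcpp::export]]
List cpp_solve_n3(NumericVector r, IntegerVector lower, IntegerVector upper,
                  int k, double tie_tol, double opt_tol, bool order_pruning) {
  const int m = r.size();
  for (int j = 0; j < m; ++j)
    if (lower[j] < 0 || upper[j] > k || lower[j] > upper[j])
      stop("infeasible bounds");
  double ncol_d = 1.0;
  for (int j = 0; j < m; ++j) ncol_d *= (upper[j] - lower[j] + 1);
  if (ncol_d > 200000.0) stop("n = 3 candidate space too large");

  // materialize all columns within bounds (row-major odometer), drop all-zero
  std::vector<std::vector<int>> cols;
  {
    std::vector<int> cur(lower.begin(), lower.end());
    while (true) {
      long long S = 0;
      for (int j = 0; j < m; ++j) S += cur[j];
      if (S > 0) cols.push_back(cur);
      int j = m - 1;
      while (j >= 0 && cur[j] == upper[j]) { cur[j] = lower[j]; --j; }
      if (j < 0) break;
      ++cur[j];
    }
  }
  const int NC = static_cast<int>(cols.size());
  std::vector<double> colsum(NC);
  std::vector<std::vector<double>> chat(NC, std::vector<double>(m));
  for (int a = 0; a < NC; ++a) {
    double S = 0;
    for (int j = 0; j < m; ++j) S += cols[a][j];
    colsum[a] = S;
    for (int j = 0; j < m; ++j) chat[a][j] = cols[a][j] / S;
  }

  // strictly-increasing order pairs of r for the pruning test
  std::vector<std::pair<int, int>> rpairs;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      if (r[i] < r[j]) rpairs.emplace_back(i, j);

  const std::vector<double> rvec(r.begin(), r.end());
  std::vector<double> c1hat(m, 1.0 / m);
  TieSet<N3Sol> ties(tie_tol);
  double count = 0.0;

  std::vector<double> u(m), v(m);
  for (int a = 0; a < NC; ++a) {
    for (int b = a; b < NC; ++b) {
      if (order_pruning) {
        bool prune = false;
        for (auto& pr : rpairs) {
          if (cols[a][pr.first] > cols[a][pr.second] &&
              cols[b][pr.first] > cols[b][pr.second]) { prune = true; break; }
        }
        if (prune) continue;
      }
      count += 1.0;
      const std::vector<double>& c2 = chat[a];
      const std::vector<double>& c3 = chat[b];
      double aa = 1.0 / 3.0, bb = 0.5;
      double nll = INF;
      for (int it = 0; it < 500; ++it) {
        // line minimization in a (weight on c2)
        for (int j = 0; j < m; ++j) {
          u[j] = (1.0 - bb) * c1hat[j] + bb * c3[j];
          v[j] = c2[j];
        }
        double n1;
        aa = segment_minimize(u, v, rvec, opt_tol, &n1);
        // line minimization in b (split between c1 and c3)
        for (int j = 0; j < m; ++j) {
          u[j] = (1.0 - aa) * c1hat[j] + aa * c2[j];
          v[j] = (1.0 - aa) * c3[j] + aa * c2[j];
        }
        double n2;
        bb = segment_minimize(u, v, rvec, opt_tol, &n2);
        if (nll - n2 < 1e-10 && it > 0) { nll = std::min(nll, n2); break; }
        nll = n2;
      }
      N3Sol s;
      s.a = a; s.b = b;
      s.mu1 = (1.0 - aa) * (1.0 - bb);
      s.mu2 = aa;
      s.mu3 = (1.0 - aa) * bb;
      ties.offer(nll, std::move(s));
    }
  }

  List sols(ties.nll.size());
  for (size_t i = 0; i < ties.nll.size(); ++i) {
    const N3Sol& s = ties.payload[i];
    IntegerVector c2v(m), c3v(m);
    for (int j = 0; j < m; ++j) {
      c2v[j] = cols[s.a][j];
      c3v[j] = cols[s.b][j];
    }
    sols[i] = List::create(
        _["c2"] = c2v, _["c3"] = c3v,
        _["mu_internal"] = NumericVector::create(s.mu1, s.mu2, s.mu3),
        _["nll"] = ties.nll[i]);
  }
  return List::create(_["count"] = count, _["best_nll"] = ties.best,
                      _["solutions"] = sols);
}
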