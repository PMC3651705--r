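#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exhaustive enumeration of all simplex grid points with denominator n in
// k dimensions (all integer compositions of n into k parts, which include
// every vertex), keeping the best point satisfying A r <= w + tol.
// Used as an independent test oracle for the LP/convex solvers, so it is
// deliberately brute force: every grid point is visited.  Partial sums
// are hoisted out of the inner loop and the feasibility check is kept
// branchless so that fine grids (n = 1000, k = 4: ~1.7e8 points) stay
// affordable.

#define ORACLE_MAX_CONS 16

struct GridCtx {
  int k, m, n;
  std::vector<double> cu;               // objective coefficient per count
  std::vector<std::vector<double>> au;  // au[h][j]: constraint coef per count
  std::vector<double> wt;               // caps + tol
  bool found;
  double best;
  std::vector<int> cnt, bestCnt;
};

static void rec_dot(GridCtx &g, int depth, int rem, double objAcc,
                    const std::vector<double> &consAcc) {
  const int m = g.m;
  if (g.k == 1 || depth == g.k - 2) {
    const int j1 = (g.k == 1) ? 0 : g.k - 2;
    const int j2 = g.k - 1;
    double ov = objAcc + rem * ((g.k == 1) ? g.cu[0] : g.cu[j2]);
    double cv[ORACLE_MAX_CONS], dv[ORACLE_MAX_CONS], wt[ORACLE_MAX_CONS];
    for (int h = 0; h < m; ++h) {
      cv[h] = consAcc[h] + rem * ((g.k == 1) ? g.au[h][0] : g.au[h][j2]);
      dv[h] = (g.k == 1) ? 0.0 : (g.au[h][j1] - g.au[h][j2]);
      wt[h] = g.wt[h];
    }
    const double od = (g.k == 1) ? 0.0 : (g.cu[j1] - g.cu[j2]);
    const int tmax = (g.k == 1) ? 0 : rem;
    for (int t = 0; t <= tmax; ++t) {
      bool ok = true;
      for (int h = 0; h < m; ++h) ok &= (cv[h] <= wt[h]);
      if (ok && ov > g.best) {
        g.found = true;
        g.best = ov;
        g.bestCnt = g.cnt;
        if (g.k > 1) {
          g.bestCnt[j1] = t;
          g.bestCnt[j2] = rem - t;
        } else {
          g.bestCnt[0] = rem;
        }
      }
      ov += od;
      for (int h = 0; h < m; ++h) cv[h] += dv[h];
    }
    return;
  }
  std::vector<double> acc(consAcc);
  double oa = objAcc;
  for (int t = 0; t <= rem; ++t) {
    g.cnt[depth] = t;
    rec_dot(g, depth + 1, rem - t, oa, acc);
    oa += g.cu[depth];
    for (int h = 0; h < m; ++h) acc[h] += g.au[h][depth];
  }
  g.cnt[depth] = 0;
}

static void init_ctx(GridCtx &g, int k, const NumericMatrix &A,
                     const NumericVector &w, int n, double tol) {
  g.k = k;
  g.m = A.nrow();
  g.n = n;
  if (g.m > ORACLE_MAX_CONS)
    stop("grid oracle supports at most %d constraints", ORACLE_MAX_CONS);
  g.found = false;
  g.best = R_NegInf;
  g.au.assign(g.m, std::vector<double>(k));
  for (int h = 0; h < g.m; ++h)
    for (int j = 0; j < k; ++j) g.au[h][j] = A(h, j) / n;
  g.wt.resize(g.m);
  for (int h = 0; h < g.m; ++h) g.wt[h] = w[h] + tol;
  g.cnt.assign(k, 0);
  g.bestCnt.assign(k, 0);
}

// [[Rcpp::export]]
List grid_search_dot(NumericVector obj, NumericMatrix A, NumericVector w,
                     int n, double tol) {
  GridCtx g;
  init_ctx(g, obj.size(), A, w, n, tol);
  g.cu.resize(g.k);
  for (int j = 0; j < g.k; ++j) g.cu[j] = obj[j] / n;
  std::vector<double> consAcc(g.m, 0.0);
  rec_dot(g, 0, n, 0.0, consAcc);
  IntegerVector cnt(g.k);
  for (int j = 0; j < g.k; ++j) cnt[j] = g.bestCnt[j];
  return List::create(_["feasible"] = g.found, _["objective"] = g.best,
                      _["counts"] = cnt);
}

static void rec_kl(GridCtx &g, const std::vector<double> &q, int depth,
                   int rem, const std::vector<double> &consAcc) {
  const int m = g.m;
  if (g.k == 1 || depth == g.k - 2) {
    const int j1 = (g.k == 1) ? 0 : g.k - 2;
    const int j2 = g.k - 1;
    double cv[ORACLE_MAX_CONS], dv[ORACLE_MAX_CONS];
    for (int h = 0; h < m; ++h) {
      cv[h] = consAcc[h] + rem * ((g.k == 1) ? g.au[h][0] : g.au[h][j2]);
      dv[h] = (g.k == 1) ? 0.0 : (g.au[h][j1] - g.au[h][j2]);
    }
    const int tmax = (g.k == 1) ? 0 : rem;
    for (int t = 0; t <= tmax; ++t) {
      bool ok = true;
      for (int h = 0; h < m; ++h) ok &= (cv[h] <= g.wt[h]);
      if (ok) {
        if (g.k > 1) {
          g.cnt[j1] = t;
          g.cnt[j2] = rem - t;
        } else {
          g.cnt[0] = rem;
        }
        double ov = 0.0;
        bool finite = true;
        for (int j = 0; j < g.k && finite; ++j) {
          if (g.cnt[j] > 0) {
            double r = (double)g.cnt[j] / g.n;
            if (q[j] <= 0.0) finite = false;
            else ov -= r * std::log(r / q[j]);
          }
        }
        if (finite && ov > g.best) {
          g.found = true;
          g.best = ov;
          g.bestCnt = g.cnt;
        }
      }
      for (int h = 0; h < m; ++h) cv[h] += dv[h];
    }
    if (g.k > 1) { g.cnt[j1] = 0; g.cnt[j2] = 0; }
    return;
  }
  std::vector<double> acc(consAcc);
  for (int t = 0; t <= rem; ++t) {
    g.cnt[depth] = t;
    rec_kl(g, q, depth + 1, rem - t, acc);
    for (int h = 0; h < m; ++h) acc[h] += g.au[h][depth];
  }
  g.cnt[depth] = 0;
}

// [[Rcpp::export]]
List grid_search_kl(NumericVector q, NumericMatrix A, NumericVector w,
                    int n, double tol) {
  GridCtx g;
  init_ctx(g, q.size(), A, w, n, tol);
  std::vector<double> qv(q.begin(), q.end());
  std::vector<double> consAcc(g.m, 0.0);
  rec_kl(g, qv, 0, n, consAcc);
  IntegerVector cnt(g.k);
  for (int j = 0; j < g.k; ++j) cnt[j] = g.bestCnt[j];
  return List::create(_["feasible"] = g.found, _["objective"] = g.best,
                      _["counts"] = cnt);
}
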