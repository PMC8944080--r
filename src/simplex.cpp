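#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-phase primal simplex with Bland's anti-cycling rule, dense tableau.
// Solves min c'x subject to A x = b, x >= 0. Small problems only (the flux
// polytopes of curated models); correctness is checked against brute-force
// vertex enumeration in the test suite.

// T is (m+1) x (ncols+1): rows 0..m-1 constraints, row m reduced costs,
// last column the right-hand side. Entering columns are restricted to
// j < n_enter (used to block artificial columns in phase 2).
static int run_simplex(NumericMatrix T, IntegerVector basis,
                       int m, int n_enter, int ncols, double eps) {
  const int max_iter = 100000;
  for (int iter = 0; iter < max_iter; ++iter) {
    int enter = -1;
    for (int j = 0; j < n_enter; ++j)
      if (T(m, j) < -eps) { enter = j; break; }   // Bland: smallest index
    if (enter < 0) return 0;                       // optimal
    int leave = -1;
    double best = 0;
    for (int i = 0; i < m; ++i) {
      if (T(i, enter) > eps) {
        double ratio = T(i, ncols) / T(i, enter);
        if (leave < 0 || ratio < best - 1e-12 ||
            (std::abs(ratio - best) <= 1e-12 && basis[i] < basis[leave])) {
          leave = i;
          best = ratio;
        }
      }
    }
    if (leave < 0) return 2;                       // unbounded
    double piv = T(leave, enter);
    for (int j = 0; j <= ncols; ++j) T(leave, j) /= piv;
    for (int i = 0; i <= m; ++i) {
      if (i == leave) continue;
      double f = T(i, enter);
      if (f != 0.0)
        for (int j = 0; j <= ncols; ++j) T(i, j) -= f * T(leave, j);
    }
    basis[leave] = enter;
  }
  return 3;                                        // iteration limit
}

// [[Rcpp::export]]
List lp_solve_cpp(NumericVector c, NumericMatrix A, NumericVector b,
                  double eps = 1e-9) {
  int m = A.nrow(), n = A.ncol();
  NumericMatrix A2(clone(A));
  NumericVector b2(clone(b));
  for (int i = 0; i < m; ++i) {
    if (b2[i] < 0) {
      for (int j = 0; j < n; ++j) A2(i, j) = -A2(i, j);
      b2[i] = -b2[i];
    }
  }

  // phase 1: artificial columns n..n+m-1, minimize their sum
  int ncols = n + m;
  NumericMatrix T(m + 1, ncols + 1);
  IntegerVector basis(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T(i, j) = A2(i, j);
    T(i, n + i) = 1.0;
    T(i, ncols) = b2[i];
    basis[i] = n + i;
  }
  for (int j = 0; j < n; ++j) {
    double s = 0;
    for (int i = 0; i < m; ++i) s += T(i, j);
    T(m, j) = -s;                                  // reduced costs
  }
  double srhs = 0;
  for (int i = 0; i < m; ++i) srhs += b2[i];
  T(m, ncols) = -srhs;

  int st = run_simplex(T, basis, m, ncols, ncols, eps);
  double phase1 = -T(m, ncols);
  if (st == 3) return List::create(_["status"] = 3);
  if (phase1 > 1e-7) return List::create(_["status"] = 1);  // infeasible

  // drive remaining artificials out of the basis where possible
  for (int i = 0; i < m; ++i) {
    if (basis[i] >= n) {
      int piv_col = -1;
      for (int j = 0; j < n; ++j)
        if (std::abs(T(i, j)) > eps) { piv_col = j; break; }
      if (piv_col < 0) continue;                   // redundant row
      double piv = T(i, piv_col);
      for (int j = 0; j <= ncols; ++j) T(i, j) /= piv;
      for (int k = 0; k <= m; ++k) {
        if (k == i) continue;
        double f = T(k, piv_col);
        if (f != 0.0)
          for (int j = 0; j <= ncols; ++j) T(k, j) -= f * T(i, j);
      }
      basis[i] = piv_col;
    }
  }

  // phase 2: rebuild the objective row for c (artificials blocked)
  for (int j = 0; j <= ncols; ++j) T(m, j) = 0.0;
  for (int j = 0; j < n; ++j) T(m, j) = c[j];
  for (int i = 0; i < m; ++i) {
    if (basis[i] < n) {
      double cb = c[basis[i]];
      if (cb != 0.0)
        for (int j = 0; j <= ncols; ++j) T(m, j) -= cb * T(i, j);
    }
  }
  st = run_simplex(T, basis, m, n, ncols, eps);
  if (st != 0) return List::create(_["status"] = st);

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) x[basis[i]] = T(i, ncols);
  double obj = 0;
  for (int j = 0; j < n; ++j) obj += c[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["value"] = obj);
}
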