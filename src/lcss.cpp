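#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Equality predicate shared by every matching kernel.  Symbols are encoded as
// integer codes on the R side, so eps == 0 reduces to exact equality and
// eps > 0 is the absolute-tolerance mode for numeric channels.
static inline bool val_eq(double a, double b, double eps) {
  if (eps <= 0.0) return a == b;
  return std::fabs(a - b) <= eps;
}

// One greedy windowed pass over a single variable.
//
// s, t   : encoded value vectors (length m, n)
// a      : 0-based suffix start in s
// sigma  : window width = number of candidate positions examined from the
//          trace pointer TP (inclusive); caller clips sigma to [1, n]
// eps    : equality tolerance (0 = exact)
//
// For each i = a..m-1 the window t[TP .. TP+sigma-1] (clipped to the end) is
// scanned left to right; the first equal position j is recorded, TP moves to
// j + 1 and i advances.  On a failed window TP stays put and i advances.
// Every predicate evaluation is counted.
// [[Rcpp::export]]
List cpp_greedy_pass(NumericVector s, NumericVector t, int a, int sigma,
                     double eps) {
  const int m = s.size(), n = t.size();
  std::vector<int> mi, mj;
  double comps = 0.0;
  int tp = 0;
  for (int i = (a < 0 ? 0 : a); i < m; ++i) {
    if (tp >= n) break;  // window empty for every remaining i: no comparisons
    int jend = (sigma >= n - tp) ? (n - 1) : (tp + sigma - 1);
    for (int j = tp; j <= jend; ++j) {
      comps += 1.0;
      if (val_eq(s[i], t[j], eps)) {
        mi.push_back(i);
        mj.push_back(j);
        tp = j + 1;
        break;
      }
    }
  }
  return List::create(_["i"] = wrap(mi), _["j"] = wrap(mj),
                      _["comparisons"] = comps);
}

// Classical dynamic-programming LCS over row tuples.
//
// A, B   : m x h and n x h encoded value matrices (h = 1 for sequences)
// eps    : per-variable tolerance (all zero = exact); rows are equal iff
//          every variable is equal
// want_trace / want_table : materialize the traceback pairs and/or the full
//          (m+1) x (n+1) table; otherwise two rolling rows are used.
//
// Traceback tie-break: diagonal (match) first, then up, then left, giving one
// deterministic canonical trace.
// [[Rcpp::export]]
List cpp_dp_lcs(NumericMatrix A, NumericMatrix B, NumericVector eps,
                bool want_trace, bool want_table) {
  const int m = A.nrow(), n = B.nrow(), h = A.ncol();
  auto rows_eq = [&](int i, int j) {
    for (int v = 0; v < h; ++v)
      if (!val_eq(A(i, v), B(j, v), eps[v])) return false;
    return true;
  };
  const double comps = (double)m * (double)n;  // one row comparison per cell

  if (!want_trace && !want_table) {
    std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
    for (int i = 1; i <= m; ++i) {
      for (int j = 1; j <= n; ++j) {
        cur[j] = rows_eq(i - 1, j - 1) ? prev[j - 1] + 1
                                       : std::max(prev[j], cur[j - 1]);
      }
      std::swap(prev, cur);
    }
    return List::create(_["length"] = prev[n], _["i"] = IntegerVector(0),
                        _["j"] = IntegerVector(0), _["comparisons"] = comps,
                        _["table"] = R_NilValue);
  }

  IntegerMatrix L(m + 1, n + 1);
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j)
      L(i, j) = rows_eq(i - 1, j - 1) ? L(i - 1, j - 1) + 1
                                      : std::max(L(i - 1, j), L(i, j - 1));

  std::vector<int> ti, tj;
  int i = m, j = n;
  while (i > 0 && j > 0) {
    if (rows_eq(i - 1, j - 1) && L(i, j) == L(i - 1, j - 1) + 1) {
      ti.push_back(i - 1);
      tj.push_back(j - 1);
      --i;
      --j;
    } else if (L(i - 1, j) >= L(i, j - 1)) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(ti.begin(), ti.end());
  std::reverse(tj.begin(), tj.end());
  return List::create(_["length"] = L(m, n), _["i"] = wrap(ti),
                      _["j"] = wrap(tj), _["comparisons"] = comps,
                      _["table"] = want_table ? (SEXP)L : (SEXP)R_NilValue);
}
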