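#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

List best_split_idx_cpp(NumericMatrix X, NumericVector y, IntegerVector idx,
                        int min_leaf);

// Exhaustive CART split search: for every feature, sort the rows, scan the
// midpoints between consecutive distinct values, and track the split that
// minimizes left SSE + right SSE subject to a minimum leaf size.  Ties are
// broken toward the lowest feature index, then the lowest threshold, so the
// tree is deterministic across platforms.
//
// Returns list(feature, threshold, sse) with feature = 0 when no admissible
// split improves on the parent node.
// [[Rcpp::export(name = ".best_split_cpp")]]
List best_split_cpp(NumericMatrix X, NumericVector y, int min_leaf) {
  IntegerVector idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i + 1;
  return best_split_idx_cpp(X, y, idx, min_leaf);
}

// Same search restricted to the rows in idx (1-based), avoiding the row-copy
// a recursive R partitioner would otherwise make at every node.
// [[Rcpp::export(name = ".best_split_idx_cpp")]]
List best_split_idx_cpp(NumericMatrix X, NumericVector y, IntegerVector idx,
                        int min_leaf) {
  const int n = idx.size(), p = X.ncol();
  double best_sse = R_PosInf, best_thr = NA_REAL;
  int best_feat = 0;

  double tot = 0.0, tot2 = 0.0;
  for (int i = 0; i < n; ++i) {
    const double yi = y[idx[i] - 1];
    tot += yi; tot2 += yi * yi;
  }
  const double parent_sse = tot2 - tot * tot / n;

  std::vector<int> ord(n);
  std::vector<double> xv(n), yv(n);

  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[i] = idx[i] - 1;
    NumericMatrix::Column col = X(_, j);
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return col[a] < col[b]; });
    for (int i = 0; i < n; ++i) { xv[i] = col[ord[i]]; yv[i] = y[ord[i]]; }

    double ls = 0.0, ls2 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      ls += yv[i]; ls2 += yv[i] * yv[i];
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf) continue;
      if (nr < min_leaf) break;
      if (xv[i + 1] <= xv[i]) continue;  // not a distinct-value boundary
      const double rs = tot - ls, rs2 = tot2 - ls2;
      const double sse = (ls2 - ls * ls / nl) + (rs2 - rs * rs / nr);
      if (sse < best_sse - 1e-12) {
        best_sse = sse;
        best_feat = j + 1;
        best_thr = (xv[i] + xv[i + 1]) / 2.0;
      }
    }
  }

  if (best_feat == 0 || best_sse >= parent_sse - 1e-12) {
    return List::create(_["feature"] = 0, _["threshold"] = NA_REAL,
                        _["sse"] = parent_sse);
  }
  return List::create(_["feature"] = best_feat, _["threshold"] = best_thr,
                      _["sse"] = best_sse);
}
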