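#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy coloring of the dual graph induced by a distance matrix at scale l.
// Dual edge (i,j) present iff d_ij >= l - tol; a proper coloring of the dual
// is a partition into boxes of pairwise distance < l. Runs one greedy pass
// per column of `orders` (1-based node permutations) and keeps the coloring
// with the fewest colors.
// [[Rcpp::export]]
List greedy_box_cover(NumericMatrix D, double l, IntegerMatrix orders,
                      double tol) {
  const int n = D.nrow();
  const int trials = orders.ncol();
  const double thresh = l - tol;

  IntegerVector counts(trials);
  std::vector<int> color(n), best_color(n);
  std::vector<int> mark(n, -1); // mark[c] == v : color c blocked for node v
  int best = n + 1;

  for (int t = 0; t < trials; ++t) {
    std::fill(color.begin(), color.end(), -1);
    int ncol = 0;
    for (int pos = 0; pos < n; ++pos) {
      const int v = orders(pos, t) - 1;
      // block colors of dual neighbours (distance >= l)
      const double *dv = &D(0, v); // column v (symmetric matrix)
      for (int u = 0; u < n; ++u) {
        if (color[u] >= 0 && dv[u] >= thresh) mark[color[u]] = t * n + pos;
      }
      int c = 0;
      while (c < ncol && mark[c] == t * n + pos) ++c;
      if (c == ncol) ++ncol;
      color[v] = c;
    }
    counts[t] = ncol;
    if (ncol < best) {
      best = ncol;
      best_color = color;
    }
  }

  IntegerVector assign(n);
  for (int i = 0; i < n; ++i) assign[i] = best_color[i] + 1;
  return List::create(_["counts"] = counts,
                      _["assignment"] = assign,
                      _["n_boxes"] = best);
}

// Exact sandbox counts for all nodes at all scales: counts(i, s) is the
// number of nodes k != i with d(i, k) <= scales[s] + tol.
// [[Rcpp::export]]
IntegerMatrix sandbox_counts_all(NumericMatrix D, NumericVector scales,
                                 double tol) {
  const int n = D.nrow();
  const int m = scales.size();
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < m; ++s) {
      const double lim = scales[s] + tol;
      int cnt = 0;
      for (int k = 0; k < n; ++k) {
        if (k != i && D(k, i) <= lim) ++cnt;
      }
      out(i, s) = cnt;
    }
  }
  return out;
}
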