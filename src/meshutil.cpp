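// Small mesh utilities kept in C++ for speed on paper-resolution grids.
#include <Rcpp.h>
using namespace Rcpp;

// Number of connected components of the element-node graph.
// [[Rcpp::export]]
int cpp_n_components(IntegerMatrix elements, int n_nodes) {
  std::vector<int> parent(n_nodes);
  for (int i = 0; i < n_nodes; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[a] = b;
  };
  int m = elements.nrow();
  for (int e = 0; e < m; ++e) {
    unite(elements(e, 0) - 1, elements(e, 1) - 1);
    unite(elements(e, 0) - 1, elements(e, 2) - 1);
  }
  std::set<int> roots;
  for (int i = 0; i < n_nodes; ++i) roots.insert(find(i));
  return (int)roots.size();
}

// First threshold crossing per node (row) of a sampled voltage record,
// linearly interpolated; upward if `upward`, else first downward crossing
// occurring at or after the per-node `after` time (NA = no constraint).
// Returns NA where no crossing exists.
// [[Rcpp::export]]
NumericVector cpp_crossing_times(NumericMatrix V, NumericVector times,
                                 double threshold, bool upward,
                                 NumericVector after) {
  int n = V.nrow(), nt = V.ncol();
  bool use_after = after.size() == n;
  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    double amin = use_after ? after[i] : NA_REAL;
    if (use_after && ISNA(amin)) continue; // undefined upstream -> masked
    for (int k = 1; k < nt; ++k) {
      double v0 = V(i, k - 1), v1 = V(i, k);
      bool hit = upward ? (v0 < threshold && v1 >= threshold)
                        : (v0 >= threshold && v1 < threshold);
      if (hit) {
        double tc = times[k - 1] + (times[k] - times[k - 1]) *
                                       (threshold - v0) / (v1 - v0);
        if (!use_after || tc >= amin) {
          out[i] = tc;
          break;
        }
      }
    }
  }
  return out;
}
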