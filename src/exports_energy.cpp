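#include "polymc_core.h"
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_min_image_dist(NumericVector p, NumericVector q,
                          NumericVector L, LogicalVector per) {
  int dim = p.size();
  double s = 0;
  for (int d = 0; d < dim; d++) {
    double dd = q[d] - p[d];
    if (per[d]) dd -= L[d] * std::round(dd / L[d]);
    s += dd * dd;
  }
  return std::sqrt(s);
}

// [[Rcpp::export]]
double cpp_total_energy(List p) {
  Sys s = make_sys(p);
  double e = s.total_energy();
  return e;
}

// [[Rcpp::export]]
double cpp_site_energy(List p, int i) {
  Sys s = make_sys(p);
  if (i < 0 || i >= s.n) stop("site index out of range");
  return s.site_local_energy(i, s.X[i]);
}

// [[Rcpp::export]]
bool cpp_has_overlap(List p, int i) {
  Sys s = make_sys(p);
  if (i >= s.n) stop("site index out of range");
  if (i < 0) return s.any_overlap();
  return s.any_overlap_site(i);
}

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; i++) parent[i] = i; }
  int find(int i) { while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; } return i; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) parent[a] = b; }
};

// single-linkage connected components under min-image distance <= linkage,
// optionally restricted to pairs with equal labels
// [[Rcpp::export]]
IntegerVector cpp_detect_clusters(List p, double linkage, IntegerVector labels) {
  Sys s = make_sys(p);
  bool use_lab = labels.size() == s.n;
  UnionFind uf(s.n);
  double l2 = linkage * linkage;
  for (int i = 0; i < s.n; i++) {
    for (int j = i + 1; j < s.n; j++) {
      if (use_lab && labels[i] != labels[j]) continue;
      if (s.dist2(i, j) <= l2) uf.unite(i, j);
    }
  }
  IntegerVector out(s.n);
  for (int i = 0; i < s.n; i++) out[i] = uf.find(i) + 1;
  return out;
}
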