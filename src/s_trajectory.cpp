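#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Largest-component sizes after every single removal, computed by running the
// removal order in reverse: vertices are re-inserted one at a time and merged
// with already-present neighbours through a union-find structure, so the whole
// trajectory costs O((N + M) * alpha) instead of N component scans.
//
// edges: M x 2 matrix of 0-based vertex indices; order: length-N 0-based
// removal order. Returns s(Q) = (largest component after the first Q
// removals) / N for Q = 1..N; s(N) is exactly 0.
// [[Rcpp::export]]
NumericVector s_trajectory_cpp(int n, IntegerMatrix edges, IntegerVector order) {
  if (n <= 0) stop("n must be positive");
  if (order.size() != n) stop("order must list every vertex exactly once");
  int m = edges.nrow();

  // CSR adjacency
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    ++deg[edges(e, 0)];
    ++deg[edges(e, 1)];
  }
  std::vector<int> ptr(n + 1, 0);
  for (int v = 0; v < n; ++v) ptr[v + 1] = ptr[v] + deg[v];
  std::vector<int> nbr(2 * (size_t)m);
  std::vector<int> fill(ptr.begin(), ptr.end() - 1);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    nbr[fill[a]++] = b;
    nbr[fill[b]++] = a;
  }

  std::vector<int> parent(n), csize(n, 1);
  std::vector<bool> active(n, false);
  for (int v = 0; v < n; ++v) parent[v] = v;

  struct UF {
    std::vector<int>& p;
    int find(int x) {
      while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
      return x;
    }
  } uf{parent};

  NumericVector s(n);
  int maxsz = 0;
  for (int k = n - 1; k >= 1; --k) {          // state after k removals
    int v = order[k];
    active[v] = true;
    for (int j = ptr[v]; j < ptr[v + 1]; ++j) {
      int u = nbr[j];
      if (!active[u]) continue;
      int ra = uf.find(v), rb = uf.find(u);
      if (ra == rb) continue;
      if (csize[ra] < csize[rb]) std::swap(ra, rb);
      parent[rb] = ra;
      csize[ra] += csize[rb];
    }
    int sz = csize[uf.find(v)];
    if (sz > maxsz) maxsz = sz;
    s[k - 1] = (double)maxsz / n;             // s(Q = k)
  }
  s[n - 1] = 0.0;                             // s(N): nothing left
  return s;
}
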