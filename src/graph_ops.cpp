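#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest path lengths (edge counts) on an undirected 0/1
// adjacency matrix by breadth-first search from every node.
// Unreachable pairs are +Inf; the diagonal is 0.
// [[Rcpp::export]]
NumericMatrix bfs_all_pairs(IntegerMatrix adj) {
  const int n = adj.nrow();
  NumericMatrix d(n, n);
  std::fill(d.begin(), d.end(), R_PosInf);
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && i != j) nb[i].push_back(j);
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    d(s, s) = 0.0;
    int head = 0, tail = 0;
    q[tail++] = s;
    while (head < tail) {
      const int u = q[head++];
      const std::vector<int>& nu = nb[u];
      for (size_t t = 0; t < nu.size(); ++t) {
        const int v = nu[t];
        if (d(s, v) == R_PosInf) {
          d(s, v) = d(s, u) + 1.0;
          q[tail++] = v;
        }
      }
    }
  }
  return d;
}

// Maslov-Sneppen degree-preserving randomization by attempted double-edge
// swaps. edges is an m x 2 matrix of 1-based node indices; nswap swaps are
// attempted; proposals creating self-loops or multi-edges are rejected.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List ms_rewire(IntegerMatrix edges, int n, int nswap) {
  const int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  // dense incidence flags; networks here are small (tens of nodes)
  std::vector<unsigned char> adj((size_t)n * n, 0);
  for (int e = 0; e < m; ++e) {
    ea[e] = edges(e, 0) - 1;
    eb[e] = edges(e, 1) - 1;
    adj[(size_t)ea[e] * n + eb[e]] = 1;
    adj[(size_t)eb[e] * n + ea[e]] = 1;
  }
  int done = 0;
  for (int it = 0; it < nswap; ++it) {
    int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
    int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int u = ea[e1], v = eb[e1];
    int x = ea[e2], y = eb[e2];
    if (unif_rand() < 0.5) std::swap(x, y);
    // proposal: (u,v),(x,y) -> (u,x),(v,y)
    if (u == x || v == y) continue;               // self-loop
    if (adj[(size_t)u * n + x] || adj[(size_t)v * n + y]) continue; // multi-edge
    adj[(size_t)u * n + v] = adj[(size_t)v * n + u] = 0;
    adj[(size_t)x * n + y] = adj[(size_t)y * n + x] = 0;
    adj[(size_t)u * n + x] = adj[(size_t)x * n + u] = 1;
    adj[(size_t)v * n + y] = adj[(size_t)y * n + v] = 1;
    ea[e1] = u; eb[e1] = x;
    ea[e2] = v; eb[e2] = y;
    ++done;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = ea[e] + 1;
    out(e, 1) = eb[e] + 1;
  }
  return List::create(_["edges"] = out, _["swaps"] = done);
}
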