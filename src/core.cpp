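#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Build adjacency lists from a 0/1 matrix (upper triangle trusted; the R
// wrappers validate symmetry).
static std::vector<std::vector<int>> adj_list(const IntegerMatrix& A) {
  const int n = A.nrow();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (A(i, j) != 0) {
        adj[i].push_back(j);
        adj[j].push_back(i);
      }
    }
  }
  return adj;
}

// All-pairs shortest path lengths of an unweighted graph by breadth-first
// search from every node; unreachable pairs are -1.
// [[Rcpp::export(name = ".bfs_distances")]]
IntegerMatrix bfs_distances_cpp(IntegerMatrix A) {
  const int n = A.nrow();
  auto adj = adj_list(A);
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), -1);
  std::vector<int> dist(n);
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    q[tail++] = s;
    while (head < tail) {
      int u = q[head++];
      for (int v : adj[u]) {
        if (dist[v] < 0) {
          dist[v] = dist[u] + 1;
          q[tail++] = v;
        }
      }
    }
    for (int j = 0; j < n; ++j) D(s, j) = dist[j];
  }
  return D;
}

// Per-node clustering coefficient 2*E_i / (k_i * (k_i - 1)); nodes with
// degree < 2 contribute 0.
// [[Rcpp::export(name = ".local_clustering")]]
NumericVector local_clustering_cpp(IntegerMatrix A) {
  const int n = A.nrow();
  auto adj = adj_list(A);
  NumericVector cc(n);
  for (int i = 0; i < n; ++i) {
    const int k = (int)adj[i].size();
    if (k < 2) { cc[i] = 0.0; continue; }
    int e = 0;
    for (int a = 0; a < k; ++a) {
      for (int b = a + 1; b < k; ++b) {
        if (A(adj[i][a], adj[i][b]) != 0) ++e;
      }
    }
    cc[i] = 2.0 * e / ((double)k * (k - 1));
  }
  return cc;
}

// Per-node local efficiency: the global efficiency of the subgraph induced
// by the neighbors of node i (node i removed); degree < 2 gives 0.
// Unreachable pairs contribute 0 to the inverse-distance sum.
//
// Neighbor subgraphs of clustered networks resolve almost every pair at
// distance 1 (an edge) or 2 (a shared neighbor), so those are answered with
// bitset intersections; only the residual pairs fall back to BFS.
// [[Rcpp::export(name = ".local_efficiency_nodes")]]
NumericVector local_efficiency_nodes_cpp(IntegerMatrix A) {
  const int n = A.nrow();
  auto adj = adj_list(A);
  NumericVector eloc(n);
  std::vector<int> sub(n, -1);     // global id -> subgraph id
  for (int i = 0; i < n; ++i) {
    const int s = (int)adj[i].size();
    if (s < 2) { eloc[i] = 0.0; continue; }
    const std::vector<int>& nb = adj[i];
    for (int a = 0; a < s; ++a) sub[nb[a]] = a;
    // neighbor-induced adjacency, as lists and as bitsets over subgraph ids
    const int words = (s + 63) / 64;
    std::vector<std::vector<int>> sadj(s);
    std::vector<uint64_t> bits((size_t)s * words, 0);
    for (int a = 0; a < s; ++a) {
      for (int v : adj[nb[a]]) {
        int b = sub[v];
        if (b >= 0 && v != nb[a]) {
          sadj[a].push_back(b);
          bits[(size_t)a * words + b / 64] |= (uint64_t)1 << (b % 64);
        }
      }
    }
    double inv_sum = 0.0;
    std::vector<std::vector<int>> pending(s);  // pairs at distance >= 3 (or disconnected)
    bool any_pending = false;
    for (int a = 0; a < s; ++a) {
      const uint64_t* ra = &bits[(size_t)a * words];
      for (int b = a + 1; b < s; ++b) {
        if (ra[b / 64] >> (b % 64) & 1) { inv_sum += 1.0; continue; }
        const uint64_t* rb = &bits[(size_t)b * words];
        bool common = false;
        for (int w = 0; w < words; ++w) {
          if (ra[w] & rb[w]) { common = true; break; }
        }
        if (common) {
          inv_sum += 0.5;
        } else {
          pending[a].push_back(b);
          any_pending = true;
        }
      }
    }
    if (any_pending) {
      std::vector<int> dist(s);
      std::vector<int> q(s);
      for (int src = 0; src < s; ++src) {
        if (pending[src].empty()) continue;
        std::fill(dist.begin(), dist.end(), -1);
        dist[src] = 0;
        int head = 0, tail = 0;
        q[tail++] = src;
        while (head < tail) {
          int u = q[head++];
          for (int v : sadj[u]) {
            if (dist[v] < 0) { dist[v] = dist[u] + 1; q[tail++] = v; }
          }
        }
        for (int b : pending[src]) {
          if (dist[b] > 0) inv_sum += 1.0 / dist[b];
        }
      }
    }
    eloc[i] = 2.0 * inv_sum / ((double)s * (s - 1));
    for (int a = 0; a < s; ++a) sub[nb[a]] = -1;
  }
  return eloc;
}

// Gaussian-kernel mass accumulation grouped by subregion: row g of the
// result is sum over vertices v in group g of exp(-((grid - x_v)/h)^2 / 2).
// The normal constant cancels in the row renormalization done in R.
// [[Rcpp::export(name = ".kde_rowsum")]]
NumericMatrix kde_rowsum_cpp(NumericVector x, IntegerVector group,
                             int n_groups, NumericVector grid, double h) {
  const int n = x.size(), g = grid.size();
  NumericMatrix M(n_groups, g);
  for (int v = 0; v < n; ++v) {
    const int r = group[v] - 1;
    for (int k = 0; k < g; ++k) {
      double z = (grid[k] - x[v]) / h;
      M(r, k) += std::exp(-0.5 * z * z);
    }
  }
  return M;
}

// Pairwise Jensen-Shannon divergence (natural log) between rows of a
// row-stochastic matrix: JSD = H(m) - (H(p) + H(q)) / 2 with m = (p + q)/2.
// [[Rcpp::export(name = ".jsd_pairwise")]]
NumericMatrix jsd_pairwise_cpp(NumericMatrix P) {
  const int n = P.nrow(), g = P.ncol();
  NumericVector H(n);
  for (int i = 0; i < n; ++i) {
    double h = 0.0;
    for (int k = 0; k < g; ++k) {
      double p = P(i, k);
      if (p > 0) h -= p * std::log(p);
    }
    H[i] = h;
  }
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double hm = 0.0;
      for (int k = 0; k < g; ++k) {
        double m = 0.5 * (P(i, k) + P(j, k));
        if (m > 0) hm -= m * std::log(m);
      }
      double d = hm - 0.5 * (H[i] + H[j]);
      if (d < 0) d = 0;                       // numerical guard
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
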