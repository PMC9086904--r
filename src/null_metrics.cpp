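// Compiled graph-metric kernels.
//
// Binary undirected graphs on up to a few hundred nodes: Watts-Strogatz
// mean local clustering, characteristic path length over connected
// ordered pairs, global/local/nodal efficiency, and Maslov-Sneppen
// degree-preserving rewired nulls. These loops run tens of thousands of
// times per subject during sparsity sweeps, hence C++.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<std::vector<int>> AdjList;

// dense 0/1 adjacency for O(1) membership tests (n is small)
struct DenseGraph {
  int n;
  std::vector<uint8_t> m;
  DenseGraph(int n_) : n(n_), m(static_cast<size_t>(n_) * n_, 0) {}
  bool has(int a, int b) const { return m[static_cast<size_t>(a) * n + b]; }
  void set(int a, int b, uint8_t v) {
    m[static_cast<size_t>(a) * n + b] = v;
    m[static_cast<size_t>(b) * n + a] = v;
  }
};

static AdjList to_lists(const std::vector<std::pair<int, int>>& elist,
                        int n) {
  AdjList adj(n);
  for (const auto& e : elist) {
    adj[e.first].push_back(e.second);
    adj[e.second].push_back(e.first);
  }
  return adj;
}

// mean WS local clustering; degree < 2 contributes 0
static double mean_clustering(const AdjList& adj, const DenseGraph& g) {
  int n = adj.size();
  double total = 0.0;
  for (int v = 0; v < n; ++v) {
    int k = adj[v].size();
    if (k < 2) continue;
    int links = 0;
    for (int i = 0; i < k; ++i) {
      for (int j = i + 1; j < k; ++j) {
        if (g.has(adj[v][i], adj[v][j])) ++links;
      }
    }
    total += (2.0 * links) / (static_cast<double>(k) * (k - 1));
  }
  return total / n;
}

// single-source BFS; dist filled with -1 for unreachable
static void bfs(const AdjList& adj, int s, std::vector<int>& dist,
                std::vector<int>& q) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[s] = 0;
  int head = 0, tail = 0;
  q[tail++] = s;
  while (head < tail) {
    int v = q[head++];
    for (int u : adj[v]) {
      if (dist[u] < 0) {
        dist[u] = dist[v] + 1;
        q[tail++] = u;
      }
    }
  }
}

// mean shortest path over connected ordered pairs
static double mean_path_length(const AdjList& adj) {
  int n = adj.size();
  long long pairs = 0, dist_sum = 0;
  std::vector<int> dist(n), q(n);
  for (int s = 0; s < n; ++s) {
    bfs(adj, s, dist, q);
    for (int v = 0; v < n; ++v) {
      if (v != s && dist[v] > 0) {
        ++pairs;
        dist_sum += dist[v];
      }
    }
  }
  if (pairs == 0) return NA_REAL;
  return static_cast<double>(dist_sum) / pairs;
}

// Cp and Lp for one edge list
// [[Rcpp::export(name = ".graph_cp_lp_cpp")]]
NumericVector graph_cp_lp_cpp(IntegerMatrix edges, int n_nodes) {
  std::vector<std::pair<int, int>> elist(edges.nrow());
  DenseGraph g(n_nodes);
  for (int e = 0; e < edges.nrow(); ++e) {
    elist[e] = std::make_pair(edges(e, 0), edges(e, 1));
    g.set(edges(e, 0), edges(e, 1), 1);
  }
  AdjList adj = to_lists(elist, n_nodes);
  return NumericVector::create(_["Cp"] = mean_clustering(adj, g),
                               _["Lp"] = mean_path_length(adj));
}

// global efficiency, nodal efficiency, local efficiency per node, and
// connectedness, in one pass
// [[Rcpp::export(name = ".efficiency_cpp")]]
List efficiency_cpp(IntegerMatrix edges, int n_nodes) {
  std::vector<std::pair<int, int>> elist(edges.nrow());
  DenseGraph g(n_nodes);
  for (int e = 0; e < edges.nrow(); ++e) {
    elist[e] = std::make_pair(edges(e, 0), edges(e, 1));
    g.set(edges(e, 0), edges(e, 1), 1);
  }
  AdjList adj = to_lists(elist, n_nodes);
  int n = n_nodes;
  std::vector<int> dist(n), q(n);
  NumericVector nodal_eff(n);
  bool connected = true;
  double inv_sum = 0.0;
  for (int s = 0; s < n; ++s) {
    bfs(adj, s, dist, q);
    double row = 0.0;
    for (int v = 0; v < n; ++v) {
      if (v == s) continue;
      if (dist[v] > 0) {
        row += 1.0 / dist[v];
      } else {
        connected = false;
      }
    }
    nodal_eff[s] = n > 1 ? row / (n - 1) : 0.0;
    inv_sum += row;
  }
  double eglob = n > 1 ? inv_sum / (static_cast<double>(n) * (n - 1)) : 0.0;

  // local efficiency: Eglob of each node's neighbor-induced subgraph
  NumericVector eloc(n);
  for (int v = 0; v < n; ++v) {
    const std::vector<int>& nb = adj[v];
    int k = nb.size();
    if (k < 2) {
      eloc[v] = 0.0;
      continue;
    }
    AdjList sub(k);
    for (int i = 0; i < k; ++i) {
      for (int j = i + 1; j < k; ++j) {
        if (g.has(nb[i], nb[j])) {
          sub[i].push_back(j);
          sub[j].push_back(i);
        }
      }
    }
    std::vector<int> sdist(k), sq(k);
    double ssum = 0.0;
    for (int s = 0; s < k; ++s) {
      bfs(sub, s, sdist, sq);
      for (int u = 0; u < k; ++u) {
        if (u != s && sdist[u] > 0) ssum += 1.0 / sdist[u];
      }
    }
    eloc[v] = ssum / (static_cast<double>(k) * (k - 1));
  }
  return List::create(_["Eglob"] = eglob, _["nodal_eff"] = nodal_eff,
                      _["Eloc"] = eloc, _["connected"] = connected);
}

// Maslov-Sneppen rewired nulls: Cp and Lp per null graph
// [[Rcpp::export(name = ".null_metrics_cpp")]]
NumericMatrix null_metrics_cpp(IntegerMatrix edges, int n_nodes,
                               int n_nulls, double swaps_per_edge,
                               int seed) {
  int n_edges = edges.nrow();
  std::mt19937 rng(static_cast<unsigned int>(seed));
  NumericMatrix out(n_nulls, 2);
  colnames(out) = CharacterVector::create("Cp", "Lp");
  std::vector<std::pair<int, int>> orig(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    orig[e] = std::make_pair(edges(e, 0), edges(e, 1));
  }
  long long attempts =
      static_cast<long long>(swaps_per_edge * n_edges + 0.5);
  std::uniform_int_distribution<int> pick(0, n_edges - 1);
  std::uniform_int_distribution<int> coin(0, 1);

  for (int b = 0; b < n_nulls; ++b) {
    std::vector<std::pair<int, int>> elist(orig);
    DenseGraph g(n_nodes);
    for (const auto& e : elist) g.set(e.first, e.second, 1);
    for (long long t = 0; t < attempts; ++t) {
      int e1 = pick(rng), e2 = pick(rng);
      if (e1 == e2) continue;
      int a = elist[e1].first, bb = elist[e1].second;
      int c = elist[e2].first, d = elist[e2].second;
      if (coin(rng)) std::swap(c, d);  // both swap orientations reachable
      // propose (a,bb),(c,d) -> (a,d),(c,bb)
      if (a == d || c == bb || a == c || bb == d) continue;
      if (g.has(a, d) || g.has(c, bb)) continue;
      g.set(a, bb, 0);
      g.set(c, d, 0);
      g.set(a, d, 1);
      g.set(c, bb, 1);
      elist[e1] = std::make_pair(a, d);
      elist[e2] = std::make_pair(c, bb);
    }
    AdjList adj = to_lists(elist, n_nodes);
    out(b, 0) = mean_clustering(adj, g);
    out(b, 1) = mean_path_length(adj);
  }
  return out;
}

// one rewired edge list, for testing the null construction itself
// [[Rcpp::export(name = ".rewire_cpp")]]
IntegerMatrix rewire_cpp(IntegerMatrix edges, int n_nodes,
                         double swaps_per_edge, int seed) {
  int n_edges = edges.nrow();
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<std::pair<int, int>> elist(n_edges);
  DenseGraph g(n_nodes);
  for (int e = 0; e < n_edges; ++e) {
    elist[e] = std::make_pair(edges(e, 0), edges(e, 1));
    g.set(edges(e, 0), edges(e, 1), 1);
  }
  long long attempts =
      static_cast<long long>(swaps_per_edge * n_edges + 0.5);
  std::uniform_int_distribution<int> pick(0, n_edges - 1);
  std::uniform_int_distribution<int> coin(0, 1);
  for (long long t = 0; t < attempts; ++t) {
    int e1 = pick(rng), e2 = pick(rng);
    if (e1 == e2) continue;
    int a = elist[e1].first, bb = elist[e1].second;
    int c = elist[e2].first, d = elist[e2].second;
    if (coin(rng)) std::swap(c, d);
    if (a == d || c == bb || a == c || bb == d) continue;
    if (g.has(a, d) || g.has(c, bb)) continue;
    g.set(a, bb, 0);
    g.set(c, d, 0);
    g.set(a, d, 1);
    g.set(c, bb, 1);
    elist[e1] = std::make_pair(a, d);
    elist[e2] = std::make_pair(c, bb);
  }
  IntegerMatrix out(n_edges, 2);
  for (int e = 0; e < n_edges; ++e) {
    out(e, 0) = elist[e].first;
    out(e, 1) = elist[e].second;
  }
  return out;
}
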