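// Hierarchical Navigable Small World (HNSW) graph index over L2-normalized
// vectors with cosine (inner-product) similarity. Standard construction:
// exponentially distributed node levels, greedy descent through upper
// layers, beam search (ef) within a layer, neighbour lists truncated to
// M (upper layers) / 2M (layer 0) by distance.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::pair<double, int> DI; // (distance, node)

static inline double dist_ip(const double *data, int d, int i, int j) {
  const double *a = data + (size_t)i * d;
  const double *b = data + (size_t)j * d;
  double s = 0.0;
  for (int k = 0; k < d; ++k) s += a[k] * b[k];
  return 1.0 - s;
}

static inline double dist_q(const double *data, int d, const double *q, int i) {
  const double *a = data + (size_t)i * d;
  double s = 0.0;
  for (int k = 0; k < d; ++k) s += a[k] * q[k];
  return 1.0 - s;
}

struct Graph {
  int N, d, M;
  const double *data;
  // adj[level][node] -> neighbour list (only nodes with levels >= level)
  std::vector< std::vector< std::vector<int> > > adj;
  std::vector<int> levels;
  int entry, max_level;
};

// beam search within one layer starting from eps; returns up to ef closest
static std::vector<DI> search_layer(const Graph &g, const double *q, int level,
                                    std::vector<int> eps, int ef,
                                    std::vector<int> &visited, int stamp) {
  std::priority_queue<DI, std::vector<DI>, std::greater<DI> > cand; // min-heap
  std::priority_queue<DI> found;                                    // max-heap
  for (int e : eps) {
    if (visited[e] == stamp) continue;
    visited[e] = stamp;
    double dd = dist_q(g.data, g.d, q, e);
    cand.push(DI(dd, e));
    found.push(DI(dd, e));
  }
  while (!cand.empty()) {
    DI c = cand.top();
    if (!found.empty() && c.first > found.top().first && (int)found.size() >= ef)
      break;
    cand.pop();
    const std::vector<int> &nb = g.adj[level][c.second];
    for (int u : nb) {
      if (visited[u] == stamp) continue;
      visited[u] = stamp;
      double dd = dist_q(g.data, g.d, q, u);
      if ((int)found.size() < ef || dd < found.top().first) {
        cand.push(DI(dd, u));
        found.push(DI(dd, u));
        if ((int)found.size() > ef) found.pop();
      }
    }
  }
  std::vector<DI> out;
  out.reserve(found.size());
  while (!found.empty()) { out.push_back(found.top()); found.pop(); }
  std::reverse(out.begin(), out.end()); // ascending distance
  return out;
}

static void shrink(const Graph &g, int level, int node, int cap) {
  std::vector<int> &nb = const_cast<Graph &>(g).adj[level][node];
  if ((int)nb.size() <= cap) return;
  std::vector<DI> ds;
  ds.reserve(nb.size());
  for (int u : nb) ds.push_back(DI(dist_ip(g.data, g.d, node, u), u));
  std::partial_sort(ds.begin(), ds.begin() + cap, ds.end());
  nb.resize(cap);
  for (int k = 0; k < cap; ++k) nb[k] = ds[k].second;
}

// [[Rcpp::export(name = ".hnsw_build")]]
List hnsw_build_cpp(NumericMatrix X, int M, int ef_construction) {
  int N = X.nrow(), d = X.ncol();
  // store row-major copy for cache-friendly scans
  std::vector<double> data((size_t)N * d);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < d; ++k) data[(size_t)i * d + k] = X(i, k);

  double mL = 1.0 / std::log((double)M);
  std::vector<int> levels(N);
  int max_possible = 0;
  for (int i = 0; i < N; ++i) {
    double u = R::unif_rand();
    if (u <= 0.0) u = 1e-12;
    levels[i] = (int)std::floor(-std::log(u) * mL);
    if (levels[i] > max_possible) max_possible = levels[i];
  }

  Graph g;
  g.N = N; g.d = d; g.M = M; g.data = data.data();
  g.adj.assign(max_possible + 1,
               std::vector< std::vector<int> >(N));
  g.levels = levels;
  g.entry = 0;
  g.max_level = levels[0];

  std::vector<int> visited(N, -1);
  int stamp = 0; // fresh visited-set stamp per layer search

  for (int i = 1; i < N; ++i) {
    const double *q = data.data() + (size_t)i * d;
    int lev = levels[i];
    int ep = g.entry;
    double ep_d = dist_q(g.data, d, q, ep);
    // greedy descent through layers above the node's level
    for (int l = g.max_level; l > lev; --l) {
      bool changed = true;
      while (changed) {
        changed = false;
        for (int u : g.adj[l][ep]) {
          double dd = dist_q(g.data, d, q, u);
          if (dd < ep_d) { ep = u; ep_d = dd; changed = true; }
        }
      }
    }
    std::vector<int> eps(1, ep);
    for (int l = std::min(lev, g.max_level); l >= 0; --l) {
      std::vector<DI> cand = search_layer(g, q, l, eps, ef_construction,
                                          visited, ++stamp);
      int cap = (l == 0) ? 2 * M : M;
      int take = std::min((int)cand.size(), M);
      std::vector<int> &own = g.adj[l][i];
      for (int k = 0; k < take; ++k) {
        int u = cand[k].second;
        own.push_back(u);
        g.adj[l][u].push_back(i);
        shrink(g, l, u, cap);
      }
      eps.clear();
      for (const DI &c : cand) eps.push_back(c.second);
      if (eps.empty()) eps.push_back(ep);
    }
    if (lev > g.max_level) { g.max_level = lev; g.entry = i; }
  }

  // export adjacency as nested lists (serializable plain R objects)
  List adj_out(g.max_level + 1);
  for (int l = 0; l <= g.max_level; ++l) {
    List ll(N);
    for (int i = 0; i < N; ++i) {
      ll[i] = IntegerVector(g.adj[l][i].begin(), g.adj[l][i].end());
    }
    adj_out[l] = ll;
  }
  return List::create(_["adjacency"] = adj_out,
                      _["levels"] = IntegerVector(levels.begin(), levels.end()),
                      _["entry"] = g.entry,
                      _["max_level"] = g.max_level,
                      _["M"] = M,
                      _["ef_construction"] = ef_construction);
}

// [[Rcpp::export(name = ".hnsw_query")]]
List hnsw_query_cpp(NumericMatrix X, List adjacency, IntegerVector levels,
                    int entry, int max_level, NumericVector query, int k,
                    int ef_search) {
  int N = X.nrow(), d = X.ncol();
  std::vector<double> data((size_t)N * d);
  for (int i = 0; i < N; ++i)
    for (int kk = 0; kk < d; ++kk) data[(size_t)i * d + kk] = X(i, kk);

  Graph g;
  g.N = N; g.d = d; g.M = 0; g.data = data.data();
  g.levels.assign(levels.begin(), levels.end());
  g.entry = entry; g.max_level = max_level;
  g.adj.resize(max_level + 1);
  for (int l = 0; l <= max_level; ++l) {
    List ll = adjacency[l];
    g.adj[l].resize(N);
    for (int i = 0; i < N; ++i) {
      IntegerVector v = ll[i];
      g.adj[l][i].assign(v.begin(), v.end());
    }
  }

  const double *q = REAL(query);
  int ep = entry;
  double ep_d = dist_q(g.data, d, q, ep);
  for (int l = max_level; l >= 1; --l) {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int u : g.adj[l][ep]) {
        double dd = dist_q(g.data, d, q, u);
        if (dd < ep_d) { ep = u; ep_d = dd; changed = true; }
      }
    }
  }
  std::vector<int> visited(N, -1);
  std::vector<int> eps(1, ep);
  int ef = std::max(ef_search, k);
  std::vector<DI> res = search_layer(g, q, 0, eps, ef, visited, 0);
  int take = std::min((int)res.size(), k);
  IntegerVector idx(take);
  NumericVector sim(take);
  for (int i = 0; i < take; ++i) {
    idx[i] = res[i].second + 1; // 1-based for R
    sim[i] = 1.0 - res[i].first;
  }
  return List::create(_["idx"] = idx, _["similarity"] = sim);
}
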