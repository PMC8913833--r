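#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Binary undirected graph primitives used throughout the small-world
// analysis. Adjacency is a 0/1 integer matrix; all functions assume symmetry
// and a zero diagonal (enforced at the R level). Graphs here are small
// (metabolite panels), so the hot paths use bitmask adjacency rows
// (n <= 32) with bit-parallel BFS; a generic BFS covers larger inputs.

// ---------- bitmask fast path (n <= 32) ----------

static inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static inline int ctz32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_ctz(x);
#else
  int c = 0; while (!(x & 1u)) { x >>= 1; ++c; } return c;
#endif
}

// sum over ordered pairs (i, j) of 1/d(i, j) within the node set `mask`,
// using adjacency restricted to `mask`; divide by m(m-1) for efficiency
static double inv_dist_sum_bits(const uint32_t *adj, uint32_t mask) {
  double acc = 0.0;
  uint32_t rest = mask;
  while (rest) {
    int i = ctz32(rest);
    rest &= rest - 1;
    uint32_t visited = 1u << i;
    uint32_t frontier = adj[i] & mask & ~visited;
    int d = 1;
    while (frontier) {
      acc += (double)popcount32(frontier) / d;
      visited |= frontier;
      uint32_t next = 0, f = frontier;
      while (f) {
        int v = ctz32(f);
        f &= f - 1;
        next |= adj[v];
      }
      frontier = next & mask & ~visited;
      ++d;
    }
  }
  return acc;
}

static double geff_bits(const uint32_t *adj, int n) {
  if (n < 2) return 0.0;
  uint32_t all = (n == 32) ? 0xffffffffu : ((1u << n) - 1u);
  return inv_dist_sum_bits(adj, all) / ((double)n * (n - 1));
}

// local efficiency of every node: efficiency of the neighbourhood-induced
// subgraph (node excluded); 0 for degree < 2
static void eloc_bits(const uint32_t *adj, int n, double *out) {
  for (int i = 0; i < n; ++i) {
    uint32_t nb = adj[i];
    int m = popcount32(nb);
    if (m < 2) {
      out[i] = 0.0;
      continue;
    }
    out[i] = inv_dist_sum_bits(adj, nb) / ((double)m * (m - 1));
  }
}

static void matrix_to_bits(const IntegerMatrix &adj, std::vector<uint32_t> &bits) {
  int n = adj.nrow();
  bits.assign(n, 0u);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && i != j) bits[i] |= (1u << j);
}

// ---------- generic path (any n) ----------

static void bfs_from(const std::vector<std::vector<int> > &nbr, int src,
                     std::vector<int> &dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  std::queue<int> q;
  q.push(src);
  while (!q.empty()) {
    int u = q.front();
    q.pop();
    for (size_t k = 0; k < nbr[u].size(); ++k) {
      int v = nbr[u][k];
      if (dist[v] < 0) {
        dist[v] = dist[u] + 1;
        q.push(v);
      }
    }
  }
}

static std::vector<std::vector<int> > adj_list(const IntegerMatrix &adj) {
  int n = adj.nrow();
  std::vector<std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && i != j) nbr[i].push_back(j);
  return nbr;
}

static double geff_generic(const IntegerMatrix &adj) {
  int n = adj.nrow();
  if (n < 2) return 0.0;
  std::vector<std::vector<int> > nbr = adj_list(adj);
  std::vector<int> dist(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    bfs_from(nbr, i, dist);
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] > 0) acc += 1.0 / dist[j];
  }
  return acc / ((double)n * (n - 1));
}

// [[Rcpp::export]]
NumericMatrix bfs_distances_cpp(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector<std::vector<int> > nbr = adj_list(adj);
  NumericMatrix out(n, n);
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) {
    bfs_from(nbr, i, dist);
    for (int j = 0; j < n; ++j)
      out(i, j) = dist[j] < 0 ? R_PosInf : (double)dist[j];
  }
  return out;
}

// [[Rcpp::export]]
double global_efficiency_cpp(IntegerMatrix adj) {
  int n = adj.nrow();
  if (n <= 32) {
    std::vector<uint32_t> bits;
    matrix_to_bits(adj, bits);
    return geff_bits(bits.data(), n);
  }
  return geff_generic(adj);
}

// [[Rcpp::export]]
NumericVector local_efficiency_cpp(IntegerMatrix adj) {
  int n = adj.nrow();
  NumericVector out(n);
  if (n <= 32) {
    std::vector<uint32_t> bits;
    matrix_to_bits(adj, bits);
    eloc_bits(bits.data(), n, REAL(out));
    return out;
  }
  // generic induced-subgraph evaluation
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && j != i) nb.push_back(j);
    int m = (int)nb.size();
    if (m < 2) {
      out[i] = 0.0;
      continue;
    }
    IntegerMatrix sub(m, m);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        sub(a, b) = (a != b && adj(nb[a], nb[b]) != 0) ? 1 : 0;
    out[i] = geff_generic(sub);
  }
  return out;
}

// Maslov-Sneppen double-edge swap on bitmask adjacency; returns the number
// of accepted swaps. Uses R's RNG so set.seed() at the R level applies.
static int swap_bits(std::vector<uint32_t> &adj,
                     std::vector<std::pair<int, int> > &edges,
                     int nswap, int max_tries) {
  int m = (int)edges.size();
  if (m < 2) return 0;
  int done = 0, tries = 0;
  while (done < nswap && tries < max_tries) {
    ++tries;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = edges[e1].first, b = edges[e1].second;
    int c = edges[e2].first, d = edges[e2].second;
    if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
    if (a == c || a == d || b == c || b == d) continue;
    if ((adj[a] >> d) & 1u) continue;
    if ((adj[c] >> b) & 1u) continue;
    adj[a] &= ~(1u << b); adj[b] &= ~(1u << a);
    adj[c] &= ~(1u << d); adj[d] &= ~(1u << c);
    adj[a] |= (1u << d); adj[d] |= (1u << a);
    adj[c] |= (1u << b); adj[b] |= (1u << c);
    edges[e1] = std::make_pair(a, d);
    edges[e2] = std::make_pair(c, b);
    ++done;
  }
  return done;
}

static void bits_to_edges(const std::vector<uint32_t> &adj, int n,
                          std::vector<std::pair<int, int> > &edges) {
  edges.clear();
  for (int i = 0; i < n; ++i) {
    // keep only j > i
    uint32_t row = adj[i] & (i == 31 ? 0u : ~((1u << (i + 1)) - 1u));
    while (row) {
      int j = ctz32(row);
      row &= row - 1;
      edges.push_back(std::make_pair(i, j));
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix double_edge_swap_cpp(IntegerMatrix adj, int nswap, int max_tries) {
  int n = adj.nrow();
  if (n > 32) stop("rewiring supports up to 32 nodes");
  std::vector<uint32_t> bits;
  matrix_to_bits(adj, bits);
  std::vector<std::pair<int, int> > edges;
  bits_to_edges(bits, n, edges);
  int done = swap_bits(bits, edges, nswap, max_tries);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = (bits[i] >> j) & 1u;
  out.attr("swaps_done") = done;
  return out;
}

// Degree-matched random ensemble: n_random independent rewirings of `adj`,
// returning each rewired network's global efficiency and mean local
// efficiency.
// [[Rcpp::export]]
List sw_ensemble_cpp(IntegerMatrix adj, int n_random, int n_swap_per_edge) {
  int n = adj.nrow();
  if (n > 32) stop("ensemble rewiring supports up to 32 nodes");
  std::vector<uint32_t> base;
  matrix_to_bits(adj, base);
  std::vector<std::pair<int, int> > base_edges;
  bits_to_edges(base, n, base_edges);
  int m = (int)base_edges.size();
  int nswap = m * n_swap_per_edge;
  int max_tries = 100 * (nswap > 0 ? nswap : 1);
  NumericVector eg(n_random), el(n_random);
  std::vector<uint32_t> work;
  std::vector<std::pair<int, int> > edges;
  std::vector<double> le(n);
  for (int r = 0; r < n_random; ++r) {
    work = base;
    edges = base_edges;
    swap_bits(work, edges, nswap, max_tries);
    eg[r] = geff_bits(work.data(), n);
    eloc_bits(work.data(), n, le.data());
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += le[i];
    el[r] = s / n;
  }
  return List::create(Named("e_global") = eg, Named("e_local_mean") = el);
}
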