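// Generic rank of the T-step structural controllability matrix
// [B, AB, ..., A^{T-1}B] with diagonal B supported on a driven-node set.
//
// Graph semantics: the generic rank equals the maximum number of
// vertex-disjoint paths in the time-expanded graph from input-injection
// vertices (one per driven node and injection time) to distinct final-layer
// state copies.  Every state copy has unit vertex capacity (node splitting),
// so the computation is a unit-capacity max flow (Dinic).
//
// Layer convention: u[k] enters x[k+1]; a column A^{T-1-k} B e_i of the
// controllability matrix corresponds to walks of length T-1-k from node i,
// entering at layer k+1 and propagated arc-by-arc to layer T.  Layer-0 state
// copies are unreachable from any injection and are omitted.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Dinic {
  int V, S, T;
  std::vector<int> head, nxt, to, cap;
  std::vector<int> level, iter;

  explicit Dinic(int V_) : V(V_), head(V_, -1) {}

  int add_edge(int u, int v, int c) {
    int id = (int)to.size();
    to.push_back(v); cap.push_back(c); nxt.push_back(head[u]); head[u] = id;
    to.push_back(u); cap.push_back(0); nxt.push_back(head[v]); head[v] = id + 1;
    return id;
  }

  bool bfs() {
    level.assign(V, -1);
    std::vector<int> q; q.reserve(V);
    q.push_back(S); level[S] = 0;
    for (size_t h = 0; h < q.size(); ++h) {
      int u = q[h];
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 0 && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push_back(to[e]);
        }
      }
    }
    return level[T] >= 0;
  }

  int dfs(int u, int f) {
    if (u == T) return f;
    for (int &e = iter[u]; e != -1; e = nxt[e]) {
      int v = to[e];
      if (cap[e] > 0 && level[v] == level[u] + 1) {
        int d = dfs(v, std::min(f, cap[e]));
        if (d > 0) { cap[e] -= d; cap[e ^ 1] += d; return d; }
      }
    }
    return 0;
  }

  // augment from the current residual state; returns added flow
  int maxflow(int s, int t) {
    S = s; T = t;
    int total = 0;
    while (bfs()) {
      iter = head;
      int f;
      while ((f = dfs(S, 1 << 30)) > 0) total += f;
    }
    return total;
  }
};

// Time-expanded flow network for an n-node pattern with horizon T.
// Vertices: source 0, sink 1, then split state copies (v, t), t = 1..T.
struct TEGraph {
  int n, T;
  Dinic din;
  // source-arc edge ids per node: src_edge[i][t-1]
  std::vector<std::vector<int>> src_edge;

  static int vcount(int n, int T) { return 2 + 2 * n * T; }
  int vin(int v, int t) const { return 2 + 2 * ((t - 1) * n + v); }
  int vout(int v, int t) const { return vin(v, t) + 1; }

  TEGraph(int n_, const IntegerMatrix &arcs, int T_, bool all_candidates)
      : n(n_), T(T_), din(vcount(n_, T_)), src_edge(n_) {
    for (int t = 1; t <= T; ++t)
      for (int v = 0; v < n; ++v)
        din.add_edge(vin(v, t), vout(v, t), 1);
    for (int t = 1; t < T; ++t)
      for (int e = 0; e < arcs.nrow(); ++e)
        din.add_edge(vout(arcs(e, 0) - 1, t), vin(arcs(e, 1) - 1, t + 1), 1);
    for (int v = 0; v < n; ++v)
      din.add_edge(vout(v, T), 1, 1);
    if (all_candidates) {
      for (int v = 0; v < n; ++v) {
        src_edge[v].reserve(T);
        for (int t = 1; t <= T; ++t)
          src_edge[v].push_back(din.add_edge(0, vin(v, t), 0));
      }
    }
  }

  void enable(int v) {  // open the T injection arcs of node v (0-based)
    for (int id : src_edge[v])
      din.cap[id] = 1;
  }
};

void check_args(int n, const IntegerMatrix &arcs, const IntegerVector &driven,
                int T) {
  if (n < 1) stop("n must be positive");
  if (T < 1) stop("T must be >= 1");
  for (int e = 0; e < arcs.nrow(); ++e)
    if (arcs(e, 0) < 1 || arcs(e, 0) > n || arcs(e, 1) < 1 || arcs(e, 1) > n)
      stop("arc endpoint out of range");
  for (int i = 0; i < driven.size(); ++i)
    if (driven[i] < 1 || driven[i] > n) stop("driven node out of range");
}

}  // namespace

// Generic rank of [B, AB, ..., A^{T-1}B] for the given pattern and driven
// set, as a max vertex-disjoint linking in the time-expanded graph.
// [[Rcpp::export]]
int cpp_generic_rank(int n, IntegerMatrix arcs, IntegerVector driven, int T) {
  check_args(n, arcs, driven, T);
  if (driven.size() == 0) return 0;
  TEGraph g(n, arcs, T, true);
  for (int i = 0; i < driven.size(); ++i) g.enable(driven[i] - 1);
  return g.din.maxflow(0, 1);
}

// Generic rank plus a certificate: the family of vertex-disjoint paths,
// each a matrix with columns (node, layer); the first row is the injection
// point (node i, layer k+1 for injection time k).
// [[Rcpp::export]]
List cpp_generic_rank_cert(int n, IntegerMatrix arcs, IntegerVector driven,
                           int T) {
  check_args(n, arcs, driven, T);
  List paths;
  if (driven.size() == 0)
    return List::create(_["rank"] = 0, _["paths"] = paths);
  TEGraph g(n, arcs, T, true);
  for (int i = 0; i < driven.size(); ++i) g.enable(driven[i] - 1);
  int rank = g.din.maxflow(0, 1);

  // walk saturated source arcs; flow on edge id e is cap[e^1] for forward ids
  Dinic &d = g.din;
  for (int v = 0; v < n; ++v) {
    for (int id : g.src_edge[v]) {
      if (d.cap[id ^ 1] == 0) continue;  // unused injection
      std::vector<int> node_seq, layer_seq;
      int cur = d.to[id];  // an in-vertex
      while (cur != 1) {
        int idx = (cur - 2) / 2;
        node_seq.push_back(idx % n + 1);
        layer_seq.push_back(idx / n + 1);
        // move through the out-vertex to the next in-vertex with flow
        int out = cur + 1;
        int nxt_v = -1;
        for (int e = d.head[out]; e != -1; e = d.nxt[e]) {
          if ((e & 1) == 0 && d.cap[e ^ 1] > 0) {
            d.cap[e ^ 1] -= 1;  // consume so shared vertices are not revisited
            nxt_v = d.to[e];
            break;
          }
        }
        if (nxt_v < 0) stop("flow decomposition failed (internal error)");
        cur = nxt_v;
      }
      IntegerMatrix pm(node_seq.size(), 2);
      for (size_t r = 0; r < node_seq.size(); ++r) {
        pm(r, 0) = node_seq[r];
        pm(r, 1) = layer_seq[r];
      }
      colnames(pm) = CharacterVector::create("node", "layer");
      paths.push_back(pm);
    }
  }
  return List::create(_["rank"] = rank, _["paths"] = paths);
}

// Greedy driven-node augmentation: starting from seed_set (possibly empty),
// repeatedly add the node with the largest generic-rank gain (ties broken by
// smallest index) until rank == n.  Flow state is maintained incrementally;
// candidate evaluation snapshots and restores the residual capacities.
// Returns the sorted driven set.
// [[Rcpp::export]]
IntegerVector cpp_min_driven_greedy(int n, IntegerMatrix arcs, int T,
                                    IntegerVector seed_set) {
  check_args(n, arcs, seed_set, T);
  TEGraph g(n, arcs, T, true);
  std::vector<bool> in_set(n, false);
  std::vector<int> chosen;
  for (int i = 0; i < seed_set.size(); ++i) {
    int v = seed_set[i] - 1;
    if (!in_set[v]) { in_set[v] = true; chosen.push_back(v); g.enable(v); }
  }
  int rank = g.din.maxflow(0, 1);
  // lazy greedy: per-candidate gain caches are upper bounds (the driven-set
  // rank function is a matroid rank, hence submodular), so a candidate whose
  // cached gain cannot strictly beat the current best is skipped; scanning
  // in index order this reproduces plain greedy exactly, including the
  // smallest-index tie-break.
  std::vector<int> gain_cache(n, std::min(T, n));
  while (rank < n) {
    int best = -1, best_gain = 0;
    std::vector<int> snap = g.din.cap;
    for (int v = 0; v < n; ++v) {
      if (in_set[v] || gain_cache[v] <= best_gain) continue;
      g.enable(v);
      int gain = g.din.maxflow(0, 1);
      g.din.cap = snap;  // rollback
      gain_cache[v] = gain;
      if (gain > best_gain) { best_gain = gain; best = v; }
      if (best_gain >= std::min(T, n - rank)) break;  // cannot do better
    }
    if (best < 0)
      stop("greedy selection stalled below full rank (internal error)");
    in_set[best] = true;
    chosen.push_back(best);
    g.enable(best);
    rank += g.din.maxflow(0, 1);
  }
  std::sort(chosen.begin(), chosen.end());
  IntegerVector out(chosen.size());
  for (size_t i = 0; i < chosen.size(); ++i) out[i] = chosen[i] + 1;
  return out;
}

// Numeric brute-force oracle: maximum rank of [B, AB, ..., A^{T-1}B] over
// random realizations of the nonzero entries (i.i.d. magnitude U(0.5, 1.5),
// random sign), using R's RNG stream.  Early exit at the structural upper
// bound min(n, |driven| * T).
// [[Rcpp::export]]
int cpp_numeric_grank(int n, IntegerMatrix arcs, IntegerVector driven, int T,
                      int trials) {
  check_args(n, arcs, driven, T);
  int d = driven.size();
  if (d == 0) return 0;
  int ub = std::min<long long>(n, (long long)d * T);
  int best = 0;
  for (int trial = 0; trial < trials && best < ub; ++trial) {
    arma::mat A(n, n, arma::fill::zeros);
    for (int e = 0; e < arcs.nrow(); ++e) {
      double w = 0.5 + unif_rand();
      if (unif_rand() < 0.5) w = -w;
      A(arcs(e, 1) - 1, arcs(e, 0) - 1) = w;
    }
    arma::mat X(n, d, arma::fill::zeros);
    for (int i = 0; i < d; ++i) {
      double b = 0.5 + unif_rand();
      if (unif_rand() < 0.5) b = -b;
      X(driven[i] - 1, i) = b;
    }
    arma::mat K(n, (size_t)d * T);
    K.cols(0, d - 1) = X;
    for (int k = 1; k < T; ++k) {
      X = A * X;
      K.cols((size_t)k * d, (size_t)(k + 1) * d - 1) = X;
    }
    int r = (int)arma::rank(K);
    if (r > best) best = r;
  }
  return best;
}
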