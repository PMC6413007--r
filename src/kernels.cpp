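#include <Rcpp.h>
#include <vector>
#include <set>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// Graph kernels shared by the descriptor layer. All edge matrices are m x 2,
// 1-based vertex indices, simple undirected graphs.

static std::vector<std::vector<int>> adj_list(int n, const IntegerMatrix &edges) {
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    adj[i].push_back(j);
    adj[j].push_back(i);
  }
  return adj;
}

// All-pairs shortest topological distances by repeated BFS.
// [[Rcpp::export]]
IntegerMatrix cpp_bfs_distances(int n, IntegerMatrix edges) {
  std::vector<std::vector<int>> adj = adj_list(n, edges);
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), NA_INTEGER);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int w : adj[v]) if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
    for (int v = 0; v < n; ++v) D(s, v) = dist[v]; // -1 marks disconnection
  }
  return D;
}

// ---- connected edge-subgraph census (Kier-Hall orders 0..4) ----------------
//
// Subgraph kinds, classified from the within-subgraph degree sequence:
//   tree (nv == ne + 1): max degree <= 2 -> path; max degree == ne -> cluster
//     (star); otherwise (one deg-3 and a deg-2 vertex, only at ne == 4) ->
//     path_cluster.
//   cyclic (nv <= ne): ring/"chain" subtype, tallied separately and excluded
//     from the three reported kinds.
// Kind codes: 0 path, 1 cluster, 2 path_cluster, 3 chain.

static int classify_subgraph(const std::vector<int> &verts,
                             const std::vector<int> &deg, int ne) {
  int nv = (int)verts.size();
  if (nv <= ne) return 3;
  int maxdeg = 0;
  for (int v : verts) if (deg[v] > maxdeg) maxdeg = deg[v];
  if (maxdeg <= 2) return 0;
  if (maxdeg == ne) return 1;
  return 2;
}

struct CensusAcc {
  // rows: order 0..4, cols: path, cluster, path_cluster, chain
  IntegerMatrix counts;
  NumericMatrix chiS, chiV;
  const NumericVector *wS, *wV;
  CensusAcc() : counts(5, 4), chiS(5, 4), chiV(5, 4) {}
};

static void accumulate(CensusAcc &acc, const IntegerMatrix &edges,
                       const std::vector<int> &eset) {
  int ne = (int)eset.size();
  std::vector<int> verts;
  static thread_local std::vector<int> deg;
  int n = (int)acc.wS->size();
  deg.assign(n, 0);
  for (int e : eset) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    if (deg[i] == 0) verts.push_back(i);
    if (deg[j] == 0) verts.push_back(j);
    deg[i]++; deg[j]++;
  }
  int kind = classify_subgraph(verts, deg, ne);
  acc.counts(ne, kind)++;
  double ps = 1.0, pv = 1.0;
  for (int v : verts) {
    ps *= 1.0 / std::sqrt((*acc.wS)[v]);
    pv *= 1.0 / std::sqrt((*acc.wV)[v]);
  }
  acc.chiS(ne, kind) += ps;
  acc.chiV(ne, kind) += pv;
}

static uint64_t pack_key(std::vector<int> ids) {
  std::sort(ids.begin(), ids.end());
  uint64_t k = 0;
  for (int id : ids) k = (k << 16) | (uint64_t)(id + 1);
  return k;
}

// Recursive growth of connected edge sets with de-duplication by sorted key.
static void grow(const IntegerMatrix &edges,
                 const std::vector<std::vector<int>> &vedges, // vertex -> edge ids
                 std::vector<int> &eset, std::vector<char> &in_set,
                 std::vector<int> &vmask, std::vector<int> &verts,
                 int max_order, std::set<uint64_t> &seen, CensusAcc &acc,
                 List *collect, int want_order) {
  int ne = (int)eset.size();
  uint64_t key = pack_key(eset);
  if (!seen.insert(key).second) return;
  if (collect == nullptr) accumulate(acc, edges, eset);
  else if (ne == want_order) {
    IntegerVector ev(eset.size());
    for (size_t k = 0; k < eset.size(); ++k) ev[k] = eset[k] + 1;
    collect->push_back(ev);
  }
  if (ne >= max_order) return;
  // frontier: edges incident to current vertex set, not already included.
  // indexed loop: recursion grows/shrinks `verts`, but restores it to the
  // first nv entries before returning
  size_t nv = verts.size();
  for (size_t vi = 0; vi < nv; ++vi) {
    int v = verts[vi];
    for (int e : vedges[v]) {
      if (in_set[e]) continue;
      in_set[e] = 1;
      eset.push_back(e);
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      bool addA = (vmask[a]++ == 0), addB = (vmask[b]++ == 0);
      if (addA) verts.push_back(a);
      if (addB) verts.push_back(b);
      grow(edges, vedges, eset, in_set, vmask, verts, max_order, seen, acc,
           collect, want_order);
      if (addB) verts.pop_back();
      if (addA) verts.pop_back();
      vmask[a]--; vmask[b]--;
      eset.pop_back();
      in_set[e] = 0;
    }
  }
}

// Census of connected edge subgraphs with 1..max_order edges, plus order-0
// vertex terms, with chi sums under simple (wS) and valence (wV) weights.
// [[Rcpp::export]]
List cpp_subgraph_census(int n, IntegerMatrix edges, NumericVector wS,
                         NumericVector wV, int max_order) {
  CensusAcc acc;
  acc.wS = &wS; acc.wV = &wV;
  // order 0: single vertices, reported under "path"
  acc.counts(0, 0) = n;
  for (int v = 0; v < n; ++v) {
    acc.chiS(0, 0) += 1.0 / std::sqrt(wS[v]);
    acc.chiV(0, 0) += 1.0 / std::sqrt(wV[v]);
  }
  int m = edges.nrow();
  std::vector<std::vector<int>> vedges(n);
  for (int e = 0; e < m; ++e) {
    vedges[edges(e, 0) - 1].push_back(e);
    vedges[edges(e, 1) - 1].push_back(e);
  }
  std::set<uint64_t> seen;
  std::vector<int> eset; std::vector<char> in_set(m, 0);
  std::vector<int> vmask(n, 0), verts;
  for (int e = 0; e < m && max_order >= 1; ++e) {
    in_set[e] = 1;
    eset.push_back(e);
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    vmask[a]++; vmask[b]++;
    verts.push_back(a); verts.push_back(b);
    grow(edges, vedges, eset, in_set, vmask, verts, max_order, seen, acc,
         nullptr, -1);
    verts.clear();
    vmask[a]--; vmask[b]--;
    eset.pop_back();
    in_set[e] = 0;
  }
  CharacterVector kinds = CharacterVector::create("path", "cluster",
                                                  "path_cluster", "chain");
  colnames(acc.counts) = kinds; colnames(acc.chiS) = kinds; colnames(acc.chiV) = kinds;
  return List::create(_["counts"] = acc.counts, _["chiS"] = acc.chiS,
                      _["chiV"] = acc.chiV);
}

// Explicit enumeration (edge-id sets) of the connected subgraphs with
// `order` edges; kind filtering is done on the R side.
// [[Rcpp::export]]
List cpp_enumerate_edge_subgraphs(int n, IntegerMatrix edges, int order) {
  List out;
  if (order < 1) return out;
  int m = edges.nrow();
  std::vector<std::vector<int>> vedges(n);
  for (int e = 0; e < m; ++e) {
    vedges[edges(e, 0) - 1].push_back(e);
    vedges[edges(e, 1) - 1].push_back(e);
  }
  NumericVector w(n, 1.0);
  CensusAcc acc; acc.wS = &w; acc.wV = &w;
  std::set<uint64_t> seen;
  std::vector<int> eset; std::vector<char> in_set(m, 0);
  std::vector<int> vmask(n, 0), verts;
  for (int e = 0; e < m; ++e) {
    in_set[e] = 1;
    eset.push_back(e);
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    vmask[a]++; vmask[b]++;
    verts.push_back(a); verts.push_back(b);
    grow(edges, vedges, eset, in_set, vmask, verts, order, seen, acc, &out,
         order);
    verts.clear();
    vmask[a]--; vmask[b]--;
    eset.pop_back();
    in_set[e] = 0;
  }
  return out;
}

// ---- longest simple paths inside one (small) biconnected block -------------

static void lp_dfs(const std::vector<std::vector<int>> &adj, int v,
                   uint64_t mask, int len, std::vector<int> &best) {
  if (len > best[v]) best[v] = len;
  for (int w : adj[v]) {
    uint64_t bit = 1ULL << w;
    if (mask & bit) continue;
    lp_dfs(adj, w, mask | bit, len + 1, best);
  }
}

// All-pairs longest-simple-path lengths by exhaustive DFS; intended for
// biconnected blocks only (caller enforces a size guard).
// [[Rcpp::export]]
IntegerMatrix cpp_block_longest_paths(int n, IntegerMatrix edges) {
  if (n > 62) stop("block too large for exhaustive detour search");
  std::vector<std::vector<int>> adj = adj_list(n, edges);
  IntegerMatrix L(n, n);
  std::vector<int> best(n);
  for (int s = 0; s < n; ++s) {
    std::fill(best.begin(), best.end(), 0);
    lp_dfs(adj, s, 1ULL << s, 0, best);
    for (int v = 0; v < n; ++v) L(s, v) = best[v];
    L(s, s) = 0;
  }
  // symmetrise (path lengths are symmetric; DFS computes both directions)
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int v = std::max(L(i, j), L(j, i));
      L(i, j) = v; L(j, i) = v;
    }
  return L;
}
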