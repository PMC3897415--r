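// Split-based tree distances and exact MAST, shared by the R-level metric
// and cloud-distance functions. Taxa are mapped to canonical indices on the
// R side (match against a common label order), so leaf bitmasks are
// comparable across trees; n_tip <= 63 so a split fits in one 64-bit word.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

typedef uint64_t u64;

static inline int popcount64(u64 x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// ---------------------------------------------------------------------------
// split tables
// ---------------------------------------------------------------------------

struct SplitTable {
  std::vector<u64> mask;     // normalized: canonical tip 1's bit never set
  std::vector<double> len;   // summed over duplicate masks (handles rooted input)
  int n_nontrivial;
  double total_len;
};

// children lists + root from an ape edge matrix
static int build_children(const IntegerMatrix& edge, int n_nodes,
                          std::vector<std::vector<int> >& ch) {
  ch.assign(n_nodes + 1, std::vector<int>());
  std::vector<char> is_child(n_nodes + 1, 0);
  for (int e = 0; e < edge.nrow(); ++e) {
    ch[edge(e, 0)].push_back(edge(e, 1));
    is_child[edge(e, 1)] = 1;
  }
  int root = -1;
  for (int v = 1; v <= n_nodes; ++v)
    if (!is_child[v] && (!ch[v].empty() || n_nodes == 1)) { root = v; break; }
  return root;
}

static void build_split_table(const IntegerMatrix& edge,
                              const NumericVector& elen,
                              const IntegerVector& tipmap, // ape tip id -> canonical id
                              int n_tip, bool rescale, SplitTable& st) {
  int n_edge = edge.nrow();
  int n_nodes = 0;
  for (int e = 0; e < n_edge; ++e)
    n_nodes = std::max(n_nodes, std::max(edge(e, 0), edge(e, 1)));
  std::vector<std::vector<int> > ch;
  int root = build_children(edge, n_nodes, ch);

  // subtree masks by iterative post-order
  std::vector<u64> mask(n_nodes + 1, 0);
  std::vector<int> order;
  order.reserve(n_nodes);
  std::vector<int> stack(1, root);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    order.push_back(u);
    for (size_t i = 0; i < ch[u].size(); ++i) stack.push_back(ch[u][i]);
  }
  int n_tip_tree = tipmap.size();
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int u = order[i];
    if (u <= n_tip_tree) mask[u] = 1ULL << (tipmap[u - 1] - 1);
    else for (size_t k = 0; k < ch[u].size(); ++k) mask[u] |= mask[ch[u][k]];
  }

  u64 full = (n_tip >= 64) ? ~0ULL : ((1ULL << n_tip) - 1);
  double total = 0.0;
  std::vector<std::pair<u64, double> > sp;
  sp.reserve(n_edge);
  for (int e = 0; e < n_edge; ++e) {
    u64 m = mask[edge(e, 1)];
    if (m & 1ULL) m ^= full;
    double l = (elen.size() == n_edge) ? elen[e] : 0.0;
    total += l;
    sp.push_back(std::make_pair(m, l));
  }
  std::sort(sp.begin(), sp.end());
  st.mask.clear(); st.len.clear();
  st.n_nontrivial = 0;
  st.total_len = total;
  double scale = (rescale && total > 0) ? 1.0 / total : 1.0;
  for (size_t i = 0; i < sp.size(); ++i) {
    if (!st.mask.empty() && st.mask.back() == sp[i].first)
      st.len.back() += sp[i].second * scale; // rooted input: merge the two root edges
    else {
      st.mask.push_back(sp[i].first);
      st.len.push_back(sp[i].second * scale);
    }
  }
  for (size_t i = 0; i < st.mask.size(); ++i) {
    int p = popcount64(st.mask[i]);
    if (std::min(p, n_tip - p) >= 2) st.n_nontrivial++;
  }
}

// metric: 0 = symmetric (non-trivial split count), 1 = RF |diff|, 2 = RF diff^2
static double pair_distance(const SplitTable& a, const SplitTable& b,
                            int n_tip, int metric) {
  size_t i = 0, j = 0;
  double acc = 0.0;
  long cnt = 0;
  while (i < a.mask.size() || j < b.mask.size()) {
    bool only_a = (j >= b.mask.size()) ||
                  (i < a.mask.size() && a.mask[i] < b.mask[j]);
    bool only_b = !only_a && ((i >= a.mask.size()) || (b.mask[j] < a.mask[i]));
    if (only_a) {
      if (metric == 0) {
        int p = popcount64(a.mask[i]);
        if (std::min(p, n_tip - p) >= 2) cnt++;
      } else if (metric == 1) acc += std::abs(a.len[i]);
      else acc += a.len[i] * a.len[i];
      ++i;
    } else if (only_b) {
      if (metric == 0) {
        int p = popcount64(b.mask[j]);
        if (std::min(p, n_tip - p) >= 2) cnt++;
      } else if (metric == 1) acc += std::abs(b.len[j]);
      else acc += b.len[j] * b.len[j];
      ++j;
    } else {
      double d = a.len[i] - b.len[j];
      if (metric == 1) acc += std::abs(d);
      else if (metric == 2) acc += d * d;
      ++i; ++j;
    }
  }
  return metric == 0 ? (double)cnt : acc;
}

// build-on-demand cache of split tables for a cloud
struct TableCache {
  const List& edges; const List& lens; const List& maps;
  int n_tip; bool rescale;
  std::vector<SplitTable> tab;
  std::vector<char> built;
  TableCache(const List& e, const List& l, const List& m, int nt, bool r)
    : edges(e), lens(l), maps(m), n_tip(nt), rescale(r),
      tab(e.size()), built(e.size(), 0) {}
  const SplitTable& get(int i) {
    if (!built[i]) {
      IntegerMatrix ed = edges[i];
      NumericVector ln = lens[i];
      IntegerVector mp = maps[i];
      build_split_table(ed, ln, mp, n_tip, rescale, tab[i]);
      built[i] = 1;
    }
    return tab[i];
  }
};

// [[Rcpp::export(name = ".cloud_pair_distances_cpp")]]
NumericVector cloud_pair_distances_cpp(List edgesA, List lensA, List mapsA,
                                       List edgesB, List lensB, List mapsB,
                                       IntegerVector ia, IntegerVector ib,
                                       int n_tip, int metric, bool rescale,
                                       bool same_cloud) {
  TableCache A(edgesA, lensA, mapsA, n_tip, rescale);
  TableCache B(edgesB, lensB, mapsB, n_tip, rescale);
  int n = ia.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    const SplitTable& ta = A.get(ia[k] - 1);
    const SplitTable& tb = same_cloud ? A.get(ib[k] - 1) : B.get(ib[k] - 1);
    out[k] = pair_distance(ta, tb, n_tip, metric);
  }
  return out;
}

// [[Rcpp::export(name = ".tree_total_lengths_cpp")]]
NumericVector tree_total_lengths_cpp(List lens) {
  int n = lens.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    NumericVector l = lens[i];
    out[i] = std::accumulate(l.begin(), l.end(), 0.0);
  }
  return out;
}

// ---------------------------------------------------------------------------
// MAST (exact, unrooted, polytomy-capable)
// ---------------------------------------------------------------------------

// Hungarian algorithm: maximum-weight assignment, rows/cols may stay
// unmatched at weight 0 (weights are non-negative subproblem sizes).
static long long assignment_max(const std::vector<std::vector<long long> >& a) {
  int n = (int)a.size(), m = (int)a[0].size();
  int N = std::max(n, m);
  const long long INF = LLONG_MAX / 4;
  std::vector<std::vector<long long> > c(N + 1, std::vector<long long>(N + 1, 0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) c[i + 1][j + 1] = -a[i][j];
  std::vector<long long> u(N + 1, 0), v(N + 1, 0), minv(N + 1);
  std::vector<int> p(N + 1, 0), way(N + 1, 0);
  for (int i = 1; i <= N; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::vector<char> used(N + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      long long delta = INF;
      for (int j = 1; j <= N; ++j) if (!used[j]) {
        long long cur = c[i0][j] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= N; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  long long cost = 0;
  for (int j = 1; j <= N; ++j) cost += c[p[j]][j];
  return -cost;
}

struct UnrootedTree {
  std::vector<std::vector<int> > adj; // 1-based node ids
  std::vector<int> can;               // ape tip id (1-based) -> canonical id
  std::vector<int> tip_of_can;        // canonical id -> ape tip id
  int n_tip, n_nodes;
};

static void build_unrooted(const IntegerMatrix& edge, const IntegerVector& tipmap,
                           int n_tip_canonical, UnrootedTree& t) {
  int n_nodes = 0;
  for (int e = 0; e < edge.nrow(); ++e)
    n_nodes = std::max(n_nodes, std::max(edge(e, 0), edge(e, 1)));
  t.n_nodes = n_nodes;
  t.n_tip = tipmap.size();
  t.adj.assign(n_nodes + 1, std::vector<int>());
  for (int e = 0; e < edge.nrow(); ++e) {
    t.adj[edge(e, 0)].push_back(edge(e, 1));
    t.adj[edge(e, 1)].push_back(edge(e, 0));
  }
  t.can.assign(t.n_tip + 1, 0);
  t.tip_of_can.assign(n_tip_canonical + 1, 0);
  for (int i = 1; i <= t.n_tip; ++i) {
    t.can[i] = tipmap[i - 1];
    t.tip_of_can[tipmap[i - 1]] = i;
  }
}

struct RootedView {
  std::vector<std::vector<int> > ch;
  std::vector<int> post;   // children before parents
  std::vector<u64> mask;   // canonical leaf masks, leaf s excluded
  int root;
};

// root the tree at the neighbour of leaf s_ape, deleting leaf s
static void build_rooted(const UnrootedTree& t, int s_ape, RootedView& rv) {
  rv.ch.assign(t.n_nodes + 1, std::vector<int>());
  rv.mask.assign(t.n_nodes + 1, 0);
  rv.post.clear();
  int root = t.adj[s_ape][0];
  rv.root = root;
  std::vector<int> parent(t.n_nodes + 1, 0), order;
  order.reserve(t.n_nodes);
  std::vector<int> stack(1, root);
  parent[root] = s_ape;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    order.push_back(u);
    for (size_t i = 0; i < t.adj[u].size(); ++i) {
      int w = t.adj[u][i];
      if (w != parent[u]) {
        parent[w] = u;
        rv.ch[u].push_back(w);
        stack.push_back(w);
      }
    }
  }
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int u = order[i];
    rv.post.push_back(u);
    if (u <= t.n_tip) rv.mask[u] = 1ULL << (t.can[u] - 1);
    else for (size_t k = 0; k < rv.ch[u].size(); ++k) rv.mask[u] |= rv.mask[rv.ch[u][k]];
  }
}

static int rooted_mast(const UnrootedTree& A, const UnrootedTree& B,
                       const RootedView& ra, const RootedView& rb) {
  std::vector<std::vector<int> > M(A.n_nodes + 1,
                                   std::vector<int>(B.n_nodes + 1, 0));
  for (size_t pu = 0; pu < ra.post.size(); ++pu) {
    int u = ra.post[pu];
    for (size_t pv = 0; pv < rb.post.size(); ++pv) {
      int v = rb.post[pv];
      int val;
      if (u <= A.n_tip) {
        val = ((rb.mask[v] >> (A.can[u] - 1)) & 1ULL) ? 1 : 0;
      } else if (v <= B.n_tip) {
        val = ((ra.mask[u] >> (B.can[v] - 1)) & 1ULL) ? 1 : 0;
      } else {
        val = 0;
        const std::vector<int>& ca = ra.ch[u];
        const std::vector<int>& cb = rb.ch[v];
        for (size_t i = 0; i < ca.size(); ++i) val = std::max(val, M[ca[i]][v]);
        for (size_t j = 0; j < cb.size(); ++j) val = std::max(val, M[u][cb[j]]);
        if (ca.size() == 2 && cb.size() == 2) {
          val = std::max(val, std::max(M[ca[0]][cb[0]] + M[ca[1]][cb[1]],
                                       M[ca[0]][cb[1]] + M[ca[1]][cb[0]]));
        } else {
          std::vector<std::vector<long long> > w(ca.size(),
              std::vector<long long>(cb.size()));
          for (size_t i = 0; i < ca.size(); ++i)
            for (size_t j = 0; j < cb.size(); ++j) w[i][j] = M[ca[i]][cb[j]];
          long long mv = assignment_max(w);
          if (mv > val) val = (int)mv;
        }
      }
      M[u][v] = val;
    }
  }
  return M[ra.root][rb.root];
}

static int mast_pair(const UnrootedTree& A, const UnrootedTree& B, int n_tip) {
  int best = 0;
  RootedView ra, rb;
  for (int s = 1; s <= n_tip; ++s) {
    build_rooted(A, A.tip_of_can[s], ra);
    build_rooted(B, B.tip_of_can[s], rb);
    int m = 1 + rooted_mast(A, B, ra, rb);
    if (m > best) best = m;
    if (best == n_tip) break;
  }
  return best;
}

// [[Rcpp::export(name = ".mast_pair_cpp")]]
int mast_pair_cpp(IntegerMatrix edgeA, IntegerVector mapA,
                  IntegerMatrix edgeB, IntegerVector mapB, int n_tip) {
  UnrootedTree A, B;
  build_unrooted(edgeA, mapA, n_tip, A);
  build_unrooted(edgeB, mapB, n_tip, B);
  return mast_pair(A, B, n_tip);
}

// Per sampled pair: d_S (symmetric), mast size, internal branch counts of
// the two trees. Backs ge_gamma() batches.
// [[Rcpp::export(name = ".gamma_pairs_cpp")]]
IntegerMatrix gamma_pairs_cpp(List edgesA, List mapsA,
                              List edgesB, List mapsB,
                              IntegerVector ia, IntegerVector ib,
                              int n_tip, bool same_cloud) {
  int nA = edgesA.size(), nB = edgesB.size();
  std::vector<UnrootedTree> TA(nA), TB(same_cloud ? 0 : nB);
  std::vector<SplitTable> SA(nA), SB(same_cloud ? 0 : nB);
  std::vector<char> bA(nA, 0), bB(same_cloud ? 0 : nB, 0);
  NumericVector dummy(0);
  int n = ia.size();
  IntegerMatrix out(n, 4);
  for (int k = 0; k < n; ++k) {
    int i = ia[k] - 1, j = ib[k] - 1;
    if (!bA[i]) {
      IntegerMatrix e = edgesA[i]; IntegerVector m = mapsA[i];
      build_unrooted(e, m, n_tip, TA[i]);
      build_split_table(e, dummy, m, n_tip, false, SA[i]);
      bA[i] = 1;
    }
    UnrootedTree* tb; SplitTable* sb;
    if (same_cloud) {
      if (!bA[j]) {
        IntegerMatrix e = edgesA[j]; IntegerVector m = mapsA[j];
        build_unrooted(e, m, n_tip, TA[j]);
        build_split_table(e, dummy, m, n_tip, false, SA[j]);
        bA[j] = 1;
      }
      tb = &TA[j]; sb = &SA[j];
    } else {
      if (!bB[j]) {
        IntegerMatrix e = edgesB[j]; IntegerVector m = mapsB[j];
        build_unrooted(e, m, n_tip, TB[j]);
        build_split_table(e, dummy, m, n_tip, false, SB[j]);
        bB[j] = 1;
      }
      tb = &TB[j]; sb = &SB[j];
    }
    out(k, 0) = (int)pair_distance(SA[i], *sb, n_tip, 0);
    out(k, 1) = mast_pair(TA[i], *tb, n_tip);
    out(k, 2) = SA[i].n_nontrivial;
    out(k, 3) = sb->n_nontrivial;
  }
  return out;
}
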