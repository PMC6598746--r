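// Five-state (A,C,G,T,gap) parsimony engine: Fitch/Hartigan scoring and
// heuristic maximum-parsimony search (random stepwise addition + NNI
// hill-climbing with plateau collection under a MaxTrees cap).
//
// State sets are bitmasks over bits 0..4; fully ambiguous characters (N)
// carry all five bits. Scoring uses Hartigan's generalisation so
// multifurcating trees are scored exactly under unit cost.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <set>
#include <cstdint>
#include <climits>
using namespace Rcpp;

namespace {

struct MPTree {
  // Rooted-at-a-leaf representation of an unrooted binary tree.
  // Leaves 0..N-1, internal nodes N..2N-3. rootLeaf is the leaf acting as
  // root; rootChild its single (internal, once >=3 leaves) neighbour.
  int N;
  int rootLeaf, rootChild;
  std::vector<int> parent, child1, child2;
  MPTree(int N_) : N(N_), rootLeaf(-1), rootChild(-1),
    parent(2 * N_ - 2, -1), child1(2 * N_ - 2, -1), child2(2 * N_ - 2, -1) {}
};

struct Scorer {
  int npat;
  int ntaxa;
  const int* w;
  std::vector<int> rowmasks; // ntaxa x npat, row-major: rowmasks[taxon*npat + p]
  std::vector<int> setbuf;   // per internal node: npat ints (reused)
  std::vector<int> order, stack;
  Scorer(const IntegerMatrix& m, const IntegerVector& wt)
    : npat(m.ncol()), ntaxa(m.nrow()), w(wt.begin()) {
    rowmasks.resize((size_t)ntaxa * npat);
    for (int i = 0; i < ntaxa; ++i)
      for (int p = 0; p < npat; ++p)
        rowmasks[(size_t)i * npat + p] = m(i, p);
    setbuf.resize((size_t)std::max(1, ntaxa - 2) * npat);
    order.reserve(2 * ntaxa);
    stack.reserve(2 * ntaxa);
  }

  int score(const MPTree& t) { return score(t, INT_MAX); }

  // early-exit scoring: any return value > bound means "worse than bound"
  int score(const MPTree& t, int bound) {
    const int N = t.N;
    // preorder over internal nodes from rootChild; walked in reverse it is
    // a valid postorder
    order.clear();
    stack.clear();
    stack.push_back(t.rootChild);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      if (t.child1[v] >= N) stack.push_back(t.child1[v]);
      if (t.child2[v] >= N) stack.push_back(t.child2[v]);
    }
    int cost = 0;
    for (int k = (int)order.size() - 1; k >= 0; --k) {
      const int v = order[k];
      const int c1 = t.child1[v], c2 = t.child2[v];
      int* out = &setbuf[(size_t)(v - N) * npat];
      const int* a = (c1 < N) ? &rowmasks[(size_t)c1 * npat]
                              : &setbuf[(size_t)(c1 - N) * npat];
      const int* b = (c2 < N) ? &rowmasks[(size_t)c2 * npat]
                              : &setbuf[(size_t)(c2 - N) * npat];
      for (int p = 0; p < npat; ++p) {
        int inter = a[p] & b[p];
        if (inter) out[p] = inter;
        else { out[p] = a[p] | b[p]; cost += w[p]; }
      }
      if (cost > bound) return cost;
    }
    // fold in the root leaf
    const int* rs = &setbuf[(size_t)(t.rootChild - N) * npat];
    const int* rl = &rowmasks[(size_t)t.rootLeaf * npat];
    for (int p = 0; p < npat; ++p)
      if (!(rs[p] & rl[p])) cost += w[p];
    return cost;
  }
};

// collect active edges as "node whose parent-edge it is" (every active node
// except the root leaf)
void active_edges(const MPTree& t, const std::vector<int>& activeInternal,
                  const std::vector<int>& activeLeaves, std::vector<int>& out) {
  out.clear();
  for (int v : activeLeaves) if (v != t.rootLeaf) out.push_back(v);
  for (int v : activeInternal) out.push_back(v);
}

inline void replace_child(MPTree& t, int par, int oldc, int newc) {
  if (par == t.rootLeaf) { t.rootChild = newc; }
  else if (t.child1[par] == oldc) t.child1[par] = newc;
  else t.child2[par] = newc;
  t.parent[newc] = par;
}

// insert leaf x with fresh internal node v on edge above node e
inline void insert_on_edge(MPTree& t, int e, int x, int v) {
  int p = t.parent[e];
  replace_child(t, p, e, v);
  t.child1[v] = e; t.child2[v] = x;
  t.parent[e] = v; t.parent[x] = v;
}

inline void remove_insertion(MPTree& t, int e, int x, int v) {
  int p = t.parent[v];
  replace_child(t, p, v, e);
  (void)x;
}

// NNI moves on internal edge (u = parent of v, both internal):
// swap sibling of v with one of v's children. which = 0 or 1.
inline void do_nni(MPTree& t, int v, int which) {
  int u = t.parent[v];
  int s = (t.child1[u] == v) ? t.child2[u] : t.child1[u];
  int c = which == 0 ? t.child1[v] : t.child2[v];
  // swap s and c
  if (t.child1[u] == s) t.child1[u] = c; else t.child2[u] = c;
  if (which == 0) t.child1[v] = s; else t.child2[v] = s;
  t.parent[c] = u; t.parent[s] = v;
}

void newick_rec(const MPTree& t, int v, std::string& out) {
  if (v < t.N) { out += "t"; out += std::to_string(v + 1); return; }
  out += "(";
  newick_rec(t, t.child1[v], out);
  out += ",";
  newick_rec(t, t.child2[v], out);
  out += ")";
}

std::string to_newick(const MPTree& t) {
  // unrooted standard form: trifurcation (rootLeaf, left(rootChild), right(rootChild))
  std::string s = "(t" + std::to_string(t.rootLeaf + 1) + ",";
  newick_rec(t, t.child1[t.rootChild], s);
  s += ",";
  newick_rec(t, t.child2[t.rootChild], s);
  s += ");";
  return s;
}

typedef std::vector<uint64_t> Split;

void collect_splits_rec(const MPTree& t, int v, int words, Split& acc,
                        std::vector<Split>& splits) {
  if (v < t.N) { acc[v >> 6] |= (uint64_t(1) << (v & 63)); return; }
  Split mine(words, 0);
  collect_splits_rec(t, t.child1[v], words, mine, splits);
  collect_splits_rec(t, t.child2[v], words, mine, splits);
  for (int i = 0; i < words; ++i) acc[i] |= mine[i];
  if (v != t.rootChild) splits.push_back(mine);
}

// canonical topology signature: sorted non-trivial splits, each normalised
// to the side not containing taxon 0
std::string signature(const MPTree& t) {
  int words = (t.N + 63) / 64;
  Split acc(words, 0);
  std::vector<Split> splits;
  collect_splits_rec(t, t.child1[t.rootChild], words, acc, splits);
  Split acc2(words, 0);
  collect_splits_rec(t, t.child2[t.rootChild], words, acc2, splits);
  Split full(words, 0);
  for (int i = 0; i < t.N; ++i) full[i >> 6] |= (uint64_t(1) << (i & 63));
  for (auto& s : splits) {
    if (s[0] & 1) for (int i = 0; i < words; ++i) s[i] = full[i] & ~s[i];
  }
  std::sort(splits.begin(), splits.end());
  std::string key;
  for (const auto& s : splits) {
    for (uint64_t wd : s) { key += std::to_string(wd); key += "."; }
    key += "|";
  }
  return key;
}

struct SearchState {
  int best;
  std::vector<std::string> newicks;
  std::set<std::string> seen;
  int maxtrees;
  void offer(const MPTree& t, int score) {
    if (score < best) { best = score; newicks.clear(); seen.clear(); }
    if (score == best && (int)newicks.size() < maxtrees) {
      std::string sig = signature(t);
      if (seen.insert(sig).second) newicks.push_back(to_newick(t));
    }
  }
};

// one full NNI hill climb; returns final score. rng used for tie-breaks.
int nni_climb(MPTree& t, Scorer& sc, std::mt19937& rng,
              const std::vector<int>& internals, int max_sweeps) {
  int cur = sc.score(t);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    int bestScore = cur;
    std::vector<std::pair<int,int>> bestMoves;
    for (int v : internals) {
      if (t.parent[v] < t.N) continue;          // parent is a leaf (root leaf)
      if (t.parent[v] == t.rootLeaf) continue;
      for (int which = 0; which < 2; ++which) {
        do_nni(t, v, which);
        int s = sc.score(t, bestScore);
        do_nni(t, v, which);                    // NNI is its own inverse
        if (s < bestScore) { bestScore = s; bestMoves.clear(); }
        if (s == bestScore && s < cur) bestMoves.push_back({v, which});
      }
    }
    if (bestScore >= cur) break;
    auto mv = bestMoves[rng() % bestMoves.size()];
    do_nni(t, mv.first, mv.second);
    cur = bestScore;
  }
  return cur;
}

// hill climb with bounded sideways (equal-cost) plateau walks: at a local
// optimum take a random equal-cost NNI and re-climb; parsimony landscapes
// are plateau-rich and pure ascent stalls on them
int nni_climb_plateau(MPTree& t, Scorer& sc, std::mt19937& rng,
                      const std::vector<int>& internals, int side_steps) {
  int cur = nni_climb(t, sc, rng, internals, 1000);
  for (int s = 0; s < side_steps; ++s) {
    std::vector<std::pair<int,int>> level;
    for (int v : internals) {
      if (t.parent[v] < t.N || t.parent[v] == t.rootLeaf) continue;
      for (int which = 0; which < 2; ++which) {
        do_nni(t, v, which);
        int sc2 = sc.score(t, cur);
        do_nni(t, v, which);
        if (sc2 == cur) level.push_back({v, which});
      }
    }
    if (level.empty()) break;
    auto mv = level[rng() % level.size()];
    do_nni(t, mv.first, mv.second);
    int improved = nni_climb(t, sc, rng, internals, 1000);
    if (improved < cur) { cur = improved; s = -1; }   // restart the budget
  }
  return cur;
}

void collect_plateau(MPTree& t, Scorer& sc, SearchState& st, int cur,
                     const std::vector<int>& internals) {
  st.offer(t, cur);
  for (int v : internals) {
    if (t.parent[v] < t.N || t.parent[v] == t.rootLeaf) continue;
    for (int which = 0; which < 2; ++which) {
      do_nni(t, v, which);
      int s = sc.score(t, st.best);
      if (s == st.best) st.offer(t, s);
      do_nni(t, v, which);
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_mp_search")]]
List cpp_mp_search(IntegerMatrix masks, IntegerVector weights,
                   int addition_replicates, int maxtrees, int seed) {
  const int N = masks.nrow();
  if (N < 4) stop("need >= 4 taxa for heuristic search");
  Scorer sc(masks, weights);
  std::mt19937 rng((uint32_t)seed);
  SearchState st; st.best = INT_MAX; st.maxtrees = maxtrees;

  for (int rep = 0; rep < addition_replicates; ++rep) {
    std::vector<int> order(N);
    for (int i = 0; i < N; ++i) order[i] = i;
    for (int i = N - 1; i > 0; --i) std::swap(order[i], order[rng() % (i + 1)]);

    MPTree t(N);
    t.rootLeaf = order[0];
    int v0 = N;
    t.rootChild = v0; t.parent[v0] = t.rootLeaf;
    t.child1[v0] = order[1]; t.child2[v0] = order[2];
    t.parent[order[1]] = v0; t.parent[order[2]] = v0;

    std::vector<int> activeLeaves = {order[0], order[1], order[2]};
    std::vector<int> activeInternal = {v0};
    std::vector<int> edges;

    for (int k = 3; k < N; ++k) {
      int x = order[k], v = N + k - 2;
      active_edges(t, activeInternal, activeLeaves, edges);
      int bestS = INT_MAX;
      std::vector<int> bestE;
      for (int e : edges) {
        insert_on_edge(t, e, x, v);
        int s = sc.score(t, bestS);
        remove_insertion(t, e, x, v);
        if (s < bestS) { bestS = s; bestE.clear(); }
        if (s == bestS) bestE.push_back(e);
      }
      insert_on_edge(t, bestE[rng() % bestE.size()], x, v);
      activeLeaves.push_back(x);
      activeInternal.push_back(v);
    }

    int cur = nni_climb_plateau(t, sc, rng, activeInternal, 2 * N);
    if (cur <= st.best) collect_plateau(t, sc, st, cur, activeInternal);
  }
  return List::create(_["best_length"] = st.best,
                      _["newicks"] = wrap(st.newicks));
}

namespace {
void exhaust_rec(MPTree& t, int k, Scorer& sc, SearchState& st,
                 std::vector<int>& activeInternal, std::vector<int>& activeLeaves) {
  const int N = t.N;
  if (k == N) {
    int s = sc.score(t, st.best);
    if (s <= st.best) st.offer(t, s);
    return;
  }
  int x = k, v = N + k - 2;
  std::vector<int> edges;
  active_edges(t, activeInternal, activeLeaves, edges);
  for (int e : edges) {
    insert_on_edge(t, e, x, v);
    activeLeaves.push_back(x); activeInternal.push_back(v);
    exhaust_rec(t, k + 1, sc, st, activeInternal, activeLeaves);
    activeLeaves.pop_back(); activeInternal.pop_back();
    remove_insertion(t, e, x, v);
  }
}
} // namespace

// [[Rcpp::export(name = ".cpp_mp_exhaustive")]]
List cpp_mp_exhaustive(IntegerMatrix masks, IntegerVector weights, int maxtrees) {
  const int N = masks.nrow();
  if (N < 4) stop("need >= 4 taxa");
  if (N > 9) stop("exhaustive search capped at 9 taxa");
  Scorer sc(masks, weights);
  SearchState st; st.best = INT_MAX; st.maxtrees = maxtrees;
  MPTree t(N);
  t.rootLeaf = 0;
  int v0 = N;
  t.rootChild = v0; t.parent[v0] = 0;
  t.child1[v0] = 1; t.child2[v0] = 2;
  t.parent[1] = v0; t.parent[2] = v0;
  std::vector<int> activeLeaves = {0, 1, 2}, activeInternal = {v0};
  exhaust_rec(t, 3, sc, st, activeInternal, activeLeaves);
  return List::create(_["best_length"] = st.best,
                      _["newicks"] = wrap(st.newicks));
}

// Hartigan scoring of an arbitrary (possibly multifurcating) rooted tree
// given in postorder edge-matrix form (ape convention, 1-based node ids,
// tips 1..nTip; tip i uses mask row i).
// [[Rcpp::export(name = ".cpp_hartigan_length")]]
int cpp_hartigan_length(IntegerMatrix edge, int nTip, int nNode,
                        IntegerMatrix masks, IntegerVector weights) {
  const int npat = masks.ncol(), ntaxa = masks.nrow();
  const int total = nTip + nNode;
  const int* w = weights.begin();
  std::vector<int> sets((size_t)total * npat, 0);
  for (int i = 0; i < nTip; ++i)
    for (int p = 0; p < npat; ++p)
      sets[(size_t)i * npat + p] = masks[i + (size_t)ntaxa * p];
  // children lists
  std::vector<std::vector<int>> kids(total);
  for (int e = 0; e < edge.nrow(); ++e)
    kids[edge(e, 0) - 1].push_back(edge(e, 1) - 1);
  int cost = 0;
  // edge matrix is postorder: parents appear after all their children's
  // subtree edges; process unique parents in row order
  std::vector<bool> done(total, false);
  for (int e = 0; e < edge.nrow(); ++e) {
    int par = edge(e, 0) - 1;
    if (done[par]) continue;
    done[par] = true;
    const auto& ch = kids[par];
    const int k = (int)ch.size();
    for (int p = 0; p < npat; ++p) {
      int cnt[5] = {0, 0, 0, 0, 0};
      for (int c : ch) {
        int s = sets[(size_t)c * npat + p];
        for (int b = 0; b < 5; ++b) if (s & (1 << b)) ++cnt[b];
      }
      int m = 0;
      for (int b = 0; b < 5; ++b) if (cnt[b] > m) m = cnt[b];
      int out = 0;
      for (int b = 0; b < 5; ++b) if (cnt[b] == m) out |= (1 << b);
      sets[(size_t)par * npat + p] = out;
      cost += (k - m) * w[p];
    }
  }
  return cost;
}

// Single-pass (or capped) NNI improvement from a given binary unrooted
// start tree, used by the reduced bootstrap-replicate search.
// edge: ape edge matrix of a binary unrooted phylo; tips 1..N map to mask rows.
// [[Rcpp::export(name = ".cpp_nni_improve")]]
List cpp_nni_improve(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                     IntegerVector weights, int sweeps, int seed) {
  const int N = nTip;
  if (N < 4) stop("need >= 4 taxa");
  // adjacency
  int maxNode = 0;
  for (int e = 0; e < edge.nrow(); ++e)
    maxNode = std::max(maxNode, std::max(edge(e, 0), edge(e, 1)));
  std::vector<std::vector<int>> adj(maxNode);
  for (int e = 0; e < edge.nrow(); ++e) {
    adj[edge(e, 0) - 1].push_back(edge(e, 1) - 1);
    adj[edge(e, 1) - 1].push_back(edge(e, 0) - 1);
  }
  MPTree t(N);
  t.rootLeaf = 0;
  // DFS from leaf 0, relabelling internal nodes N..2N-3
  std::vector<int> mapId(maxNode, -1);
  int nextInternal = N;
  std::vector<int> internals;
  // iterative DFS assigning children
  std::vector<std::pair<int,int>> stack; // (orig node, orig parent)
  int start = adj[0][0];
  stack.push_back({start, 0});
  t.parent[0] = -1;
  while (!stack.empty()) {
    auto pr = stack.back(); stack.pop_back();
    int orig = pr.first, origPar = pr.second;
    int my;
    if (orig < N) my = orig;
    else { my = nextInternal++; internals.push_back(my); }
    mapId[orig] = my;
    int parMapped = (origPar == 0) ? 0 : mapId[origPar];
    if (origPar == 0) { t.rootChild = my; t.parent[my] = 0; }
    else {
      t.parent[my] = parMapped;
      if (t.child1[parMapped] == -1) t.child1[parMapped] = my;
      else if (t.child2[parMapped] == -1) t.child2[parMapped] = my;
      else stop("input tree is not binary");
    }
    for (int nb : adj[orig]) if (nb != origPar) stack.push_back({nb, orig});
  }
  Scorer sc(masks, weights);
  std::mt19937 rng((uint32_t)seed);
  int final_score = nni_climb(t, sc, rng, internals, sweeps);
  return List::create(_["best_length"] = final_score,
                      _["newick"] = to_newick(t));
}
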