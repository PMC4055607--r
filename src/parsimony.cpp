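#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Trees are passed as a parent vector (0-based node ids, -1 for the root) and
// a taxon vector mapping each node to a row of the state matrix (-1 for
// internal nodes). States are coded 0, 1, 2 (= missing "?", i.e. {0,1}).
// Costs are unit; scoring is the two-state Sankoff dynamic programme, which
// equals Fitch on bifurcations and handles multifurcations exactly.

static const int BIG = 1 << 24; // saturating "forbidden" cost

static std::vector<int> order_by_depth(const std::vector<int>& par) {
  int m = (int)par.size();
  std::vector<int> depth(m, 0), order(m);
  for (int i = 0; i < m; ++i) {
    int d = 0, v = i;
    while (par[v] >= 0) {
      v = par[v];
      ++d;
      if (d > m) stop("cycle in parent vector");
    }
    depth[i] = d;
  }
  std::iota(order.begin(), order.end(), 0);
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return depth[a] > depth[b]; });
  return order;
}

static void sankoff_core(const std::vector<int>& par,
                         const std::vector<int>& taxon,
                         const IntegerMatrix& states,
                         std::vector<int>& out) {
  int m = (int)par.size(), nc = states.ncol();
  std::vector<int> c0((size_t)m * nc, 0), c1((size_t)m * nc, 0);
  for (int v = 0; v < m; ++v) {
    int t = taxon[v];
    if (t < 0) continue;
    for (int j = 0; j < nc; ++j) {
      int s = states(t, j);
      if (s == 1) c0[(size_t)v * nc + j] = BIG;
      else if (s == 0) c1[(size_t)v * nc + j] = BIG;
    }
  }
  std::vector<int> ord = order_by_depth(par);
  int root = -1;
  for (int idx = 0; idx < m; ++idx) {
    int v = ord[idx], p = par[v];
    if (p == -1) { root = v; continue; }
    if (p < -1) continue; // node not in use (enumeration pool)
    size_t ov = (size_t)v * nc, op = (size_t)p * nc;
    for (int j = 0; j < nc; ++j) {
      int a = c0[ov + j], b = c1[ov + j];
      int add0 = std::min(a, b + 1), add1 = std::min(b, a + 1);
      c0[op + j] = std::min(c0[op + j] + add0, BIG);
      c1[op + j] = std::min(c1[op + j] + add1, BIG);
    }
  }
  if (root < 0) stop("no root in parent vector");
  out.resize(nc);
  size_t orr = (size_t)root * nc;
  for (int j = 0; j < nc; ++j) out[j] = std::min(c0[orr + j], c1[orr + j]);
}

// [[Rcpp::export]]
IntegerVector sankoff_lengths_cpp(IntegerVector parent, IntegerVector taxon,
                                  IntegerMatrix states) {
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<int> tax(taxon.begin(), taxon.end());
  std::vector<int> lens;
  sankoff_core(par, tax, states, lens);
  return wrap(lens);
}

// [[Rcpp::export]]
int sankoff_total_cpp(IntegerVector parent, IntegerVector taxon,
                      IntegerMatrix states) {
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<int> tax(taxon.begin(), taxon.end());
  std::vector<int> lens;
  sankoff_core(par, tax, states, lens);
  return std::accumulate(lens.begin(), lens.end(), 0);
}

// [[Rcpp::export]]
IntegerVector sankoff_many_cpp(List parents, IntegerVector taxon,
                               IntegerMatrix states) {
  int k = parents.size();
  IntegerVector out(k);
  std::vector<int> tax(taxon.begin(), taxon.end());
  std::vector<int> lens;
  for (int i = 0; i < k; ++i) {
    IntegerVector pv = parents[i];
    std::vector<int> par(pv.begin(), pv.end());
    sankoff_core(par, tax, states, lens);
    out[i] = std::accumulate(lens.begin(), lens.end(), 0);
  }
  return out;
}

// Exhaustive enumeration of rooted binary ingroup topologies with the
// outgroup constrained basal. Node layout (0-based):
//   0..n-1      ingroup leaves (taxon = ingroup[i])
//   n           outgroup leaf
//   n+1         global root (children: outgroup, ingroup subtree)
//   n+2..2n     internal node pool, node n+1+k created when leaf k is added
struct ExhaustiveState {
  int n, nc, root, outnode;
  std::vector<int> par, taxon, usable;
  const IntegerMatrix* states;
  long long n_scored = 0;
  int best = INT_MAX;
  int max_keep;
  bool truncated = false;
  std::vector<std::vector<int>> best_trees;
};

static void exhaustive_rec(ExhaustiveState& st, int k) {
  if (k == st.n) {
    std::vector<int> lens;
    sankoff_core(st.par, st.taxon, *st.states, lens);
    int tot = std::accumulate(lens.begin(), lens.end(), 0);
    ++st.n_scored;
    if (tot < st.best) {
      st.best = tot;
      st.best_trees.clear();
      st.truncated = false;
    }
    if (tot == st.best) {
      if ((int)st.best_trees.size() < st.max_keep) st.best_trees.push_back(st.par);
      else st.truncated = true;
    }
    return;
  }
  int u = st.n + 1 + k; // fresh internal node
  size_t nus = st.usable.size();
  for (size_t i = 0; i < nus; ++i) {
    int v = st.usable[i];
    int pv = st.par[v];
    st.par[u] = pv;
    st.par[v] = u;
    st.par[k] = u;
    st.usable.push_back(u);
    st.usable.push_back(k);
    exhaustive_rec(st, k + 1);
    st.usable.pop_back();
    st.usable.pop_back();
    st.par[v] = pv;
    st.par[u] = -2;
  }
}

// [[Rcpp::export]]
List exhaustive_cpp(IntegerMatrix states, IntegerVector ingroup, int outgroup,
                    int max_keep) {
  int n = ingroup.size();
  if (n < 1) stop("need at least one ingroup taxon");
  ExhaustiveState st;
  st.n = n;
  st.nc = states.ncol();
  st.states = &states;
  st.max_keep = max_keep;
  int m = 2 * n + 1;
  st.par.assign(m, -2);
  st.taxon.assign(m, -1);
  for (int i = 0; i < n; ++i) st.taxon[i] = ingroup[i];
  st.outnode = n;
  st.taxon[st.outnode] = outgroup;
  st.root = n + 1;
  st.par[st.root] = -1;
  st.par[st.outnode] = st.root;
  st.par[0] = st.root; // first ingroup leaf hangs off the root
  st.usable.push_back(0);
  exhaustive_rec(st, 1);
  List trees(st.best_trees.size());
  for (size_t i = 0; i < st.best_trees.size(); ++i)
    trees[i] = wrap(st.best_trees[i]);
  return List::create(_["best_length"] = st.best,
                      _["n_scored"] = (double)st.n_scored,
                      _["taxon"] = wrap(st.taxon),
                      _["trees"] = trees,
                      _["truncated"] = st.truncated);
}
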