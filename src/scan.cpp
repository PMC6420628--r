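#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Internal tree representation used by the scan hot path.
// Leaves are 0..n-1; internal nodes are appended as they are created.

namespace {

struct Unrooted {
  int n; // leaves
  std::vector<std::vector<std::pair<int, double>>> adj;
};

// Saitou-Nei neighbor joining with deterministic tie-breaking: among
// joins with equal Q, the pair whose (smaller, larger) priority ranks
// are lexicographically lowest is joined first.  Negative branch-length
// estimates are clamped to zero; internal cluster distances are kept
// as computed.
Unrooted nj_agglomerate(const std::vector<std::vector<double>>& D0,
                        const std::vector<int>& prio0) {
  const int n = (int)D0.size();
  if (n < 3) stop("neighbor joining needs at least 3 taxa");
  const int ntot = 2 * n - 2;
  std::vector<std::vector<double>> D(ntot, std::vector<double>(ntot, 0.0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D[i][j] = D0[i][j];
  std::vector<int> prio(ntot, 0);
  for (int i = 0; i < n; ++i) prio[i] = prio0[i];

  Unrooted tr;
  tr.n = n;
  tr.adj.assign(ntot, {});
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;
  int next_id = n;

  auto link = [&](int a, int b, double len) {
    if (len < 0) len = 0;
    tr.adj[a].push_back({b, len});
    tr.adj[b].push_back({a, len});
  };

  while ((int)act.size() > 3) {
    const int m = (int)act.size();
    std::vector<double> r(m, 0.0);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b) r[a] += D[act[a]][act[b]];
    double bestQ = R_PosInf;
    int bi = -1, bj = -1;
    int bplo = -1, bphi = -1;
    for (int a = 0; a < m; ++a) {
      for (int b = a + 1; b < m; ++b) {
        double Q = (m - 2) * D[act[a]][act[b]] - r[a] - r[b];
        int plo = std::min(prio[act[a]], prio[act[b]]);
        int phi = std::max(prio[act[a]], prio[act[b]]);
        bool take = false;
        if (Q < bestQ) take = true;
        else if (Q == bestQ && (plo < bplo || (plo == bplo && phi < bphi)))
          take = true;
        if (take) { bestQ = Q; bi = a; bj = b; bplo = plo; bphi = phi; }
      }
    }
    const int i = act[bi], j = act[bj];
    const int u = next_id++;
    double li = 0.5 * D[i][j] + (r[bi] - r[bj]) / (2.0 * (m - 2));
    double lj = D[i][j] - li;
    link(u, i, li);
    link(u, j, lj);
    for (int a = 0; a < m; ++a) {
      if (a == bi || a == bj) continue;
      const int k = act[a];
      D[u][k] = D[k][u] = 0.5 * (D[i][k] + D[j][k] - D[i][j]);
    }
    prio[u] = bplo;
    // replace i, j by u in the active list (keep order stable)
    std::vector<int> nact;
    nact.reserve(m - 1);
    for (int a = 0; a < m; ++a)
      if (a != bi && a != bj) nact.push_back(act[a]);
    nact.push_back(u);
    act.swap(nact);
  }

  // final three-way join
  const int i = act[0], j = act[1], k = act[2];
  const int c = next_id++;
  link(c, i, 0.5 * (D[i][j] + D[i][k] - D[j][k]));
  link(c, j, 0.5 * (D[i][j] + D[j][k] - D[i][k]));
  link(c, k, 0.5 * (D[i][k] + D[j][k] - D[i][j]));
  return tr;
}

struct Rooted {
  int n;        // leaves 0..n-1
  int nnode;    // total nodes
  int root;
  std::vector<int> kid1, kid2; // -1 for leaves
};

// Distances and parent pointers from a start node over the adjacency.
void walk_from(const Unrooted& tr, int start, std::vector<double>& dist,
               std::vector<int>& parent) {
  const int N = (int)tr.adj.size();
  dist.assign(N, -1.0);
  parent.assign(N, -1);
  std::vector<int> stack{start};
  dist[start] = 0.0;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (auto& e : tr.adj[v]) {
      if (dist[e.first] < 0) {
        dist[e.first] = dist[v] + e.second;
        parent[e.first] = v;
        stack.push_back(e.first);
      }
    }
  }
}

double edge_len(const Unrooted& tr, int a, int b) {
  for (auto& e : tr.adj[a]) if (e.first == b) return e.second;
  return 0.0;
}

// Midpoint rooting: root is placed halfway along the longest
// leaf-to-leaf path.  Ties on the path ends resolve to the lowest leaf
// indices so repeated runs are identical.
Rooted midpoint_root(const Unrooted& tr, std::vector<double>* out_rlen = nullptr) {
  const int n = tr.n;
  std::vector<double> dist;
  std::vector<int> parent;
  int bu = 0, bv = 0;
  double bd = -1.0;
  for (int u = 0; u < n; ++u) {
    walk_from(tr, u, dist, parent);
    for (int v = u + 1; v < n; ++v)
      if (dist[v] > bd) { bd = dist[v]; bu = u; bv = v; }
  }
  // path from bu to bv
  walk_from(tr, bu, dist, parent);
  std::vector<int> path;
  for (int v = bv; v != -1; v = parent[v]) path.push_back(v);
  std::reverse(path.begin(), path.end()); // bu ... bv
  const double target = bd / 2.0;
  // find edge (path[e], path[e+1]) containing the midpoint
  int ea = path[0], eb = path.size() > 1 ? path[1] : path[0];
  double offset = 0.0; // distance from ea to root along that edge
  double cum = 0.0;
  for (size_t s = 0; s + 1 < path.size(); ++s) {
    double L = edge_len(tr, path[s], path[s + 1]);
    if (cum + L >= target || s + 2 == path.size()) {
      ea = path[s]; eb = path[s + 1];
      offset = std::min(std::max(target - cum, 0.0), L);
      break;
    }
    cum += L;
  }

  // orient the tree away from a new root placed on edge (ea, eb)
  const int N = (int)tr.adj.size();
  Rooted rt;
  rt.n = n;
  rt.nnode = N + 1;
  rt.root = N;
  rt.kid1.assign(N + 1, -1);
  rt.kid2.assign(N + 1, -1);
  std::vector<double> rlen(N + 1, 0.0); // branch length above each node
  double Lab = edge_len(tr, ea, eb);
  rt.kid1[rt.root] = ea;
  rt.kid2[rt.root] = eb;
  rlen[ea] = offset;
  rlen[eb] = Lab - offset;
  // DFS orienting both halves
  std::vector<int> stack;
  std::vector<int> par(N, -1);
  par[ea] = rt.root; par[eb] = rt.root;
  stack.push_back(ea); stack.push_back(eb);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (auto& e : tr.adj[v]) {
      int w = e.first;
      if (w == par[v]) continue;
      if (par[v] == rt.root &&
          ((v == ea && w == eb) || (v == eb && w == ea))) continue;
      par[w] = v;
      rlen[w] = e.second;
      if (rt.kid1[v] < 0) rt.kid1[v] = w; else rt.kid2[v] = w;
      stack.push_back(w);
    }
  }
  if (out_rlen) *out_rlen = rlen;
  return rt;
}

// Ancestral-genotype reconstruction rules.  State codes:
//   0 / 1 : reference / alternate genotype
//   -1    : EVENT (children disagreed; one independent emergence counted
//           when the event is created, never when two EVENTs merge)
//   -9    : no information (all leaves below are missing; equivalent to
//           pruning those leaves from the tree)
int count_emergences(const Rooted& rt, const std::vector<int>& leaf_state) {
  std::vector<int> st(rt.nnode, -9);
  int events = 0;
  // iterative postorder
  std::vector<int> stack{rt.root}, order;
  order.reserve(rt.nnode);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    if (rt.kid1[v] >= 0) { stack.push_back(rt.kid1[v]); stack.push_back(rt.kid2[v]); }
  }
  for (int idx = (int)order.size() - 1; idx >= 0; --idx) {
    int v = order[idx];
    if (rt.kid1[v] < 0) { // leaf
      st[v] = (v < rt.n) ? leaf_state[v] : -9;
      continue;
    }
    int a = st[rt.kid1[v]], b = st[rt.kid2[v]];
    if (a == -9 && b == -9) st[v] = -9;
    else if (a == -9) st[v] = b;
    else if (b == -9) st[v] = a;
    else if (a == -1 && b == -1) st[v] = -1;
    else if (a == -1) st[v] = b;
    else if (b == -1) st[v] = a;
    else if (a == b) st[v] = a;
    else { st[v] = -1; ++events; }
  }
  return events;
}

// Pairwise discordance update for one variant column: +delta to every
// pair of strains that are both called and disagree.
inline void update_pairs(std::vector<std::vector<double>>& D,
                         const IntegerMatrix& calls, int col, double delta) {
  const int S = calls.nrow();
  for (int a = 0; a < S; ++a) {
    int ca = calls(a, col);
    if (ca == NA_INTEGER) continue;
    for (int b = a + 1; b < S; ++b) {
      int cb = calls(b, col);
      if (cb == NA_INTEGER || ca == cb) continue;
      D[a][b] += delta;
      D[b][a] += delta;
    }
  }
}

List rooted_to_phylo(const Rooted& rt, const std::vector<double>& rlen) {
  // ape numbering: tips 1..n, root n+1, further internals in preorder
  const int n = rt.n;
  std::vector<int> ape_id(rt.nnode, 0);
  for (int i = 0; i < n; ++i) ape_id[i] = i + 1;
  int next_int = n + 1;
  std::vector<std::array<int, 2>> edges;
  std::vector<double> elen;
  std::vector<int> stack{rt.root};
  ape_id[rt.root] = next_int++;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (int kid : {rt.kid1[v], rt.kid2[v]}) {
      if (kid < 0) continue;
      if (rt.kid1[kid] >= 0) ape_id[kid] = next_int++;
      edges.push_back({ape_id[v], ape_id[kid]});
      elen.push_back(rlen[kid]);
      stack.push_back(kid);
    }
  }
  IntegerMatrix em((int)edges.size(), 2);
  NumericVector el((int)edges.size());
  for (int i = 0; i < (int)edges.size(); ++i) {
    em(i, 0) = edges[i][0];
    em(i, 1) = edges[i][1];
    el[i] = elen[i];
  }
  return List::create(_["edge"] = em, _["edge.length"] = el,
                      _["Nnode"] = rt.nnode - n);
}

std::vector<std::vector<double>> as_dmat(const NumericMatrix& D) {
  const int n = D.nrow();
  std::vector<std::vector<double>> d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i][j] = D(i, j);
  return d;
}

std::vector<int> as_prio(const IntegerVector& p) {
  return std::vector<int>(p.begin(), p.end());
}

} // namespace

//' @useDynLib homoplasr, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export]]
List nj_unrooted_cpp(NumericMatrix D, IntegerVector prio) {
  Unrooted tr = nj_agglomerate(as_dmat(D), as_prio(prio));
  // emit as an unrooted ape tree: basal node is the last created one
  const int n = tr.n;
  const int basal = (int)tr.adj.size() - 1;
  std::vector<int> ape_id(tr.adj.size(), 0);
  for (int i = 0; i < n; ++i) ape_id[i] = i + 1;
  int next_int = n + 1;
  ape_id[basal] = next_int++;
  std::vector<std::array<int, 2>> edges;
  std::vector<double> elen;
  std::vector<int> stack{basal};
  std::vector<int> par(tr.adj.size(), -1);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (auto& e : tr.adj[v]) {
      int w = e.first;
      if (w == par[v]) continue;
      par[w] = v;
      if (w >= n) ape_id[w] = next_int++;
      edges.push_back({ape_id[v], ape_id[w]});
      elen.push_back(e.second);
      stack.push_back(w);
    }
  }
  IntegerMatrix em((int)edges.size(), 2);
  NumericVector el((int)edges.size());
  for (int i = 0; i < (int)edges.size(); ++i) {
    em(i, 0) = edges[i][0]; em(i, 1) = edges[i][1]; el[i] = elen[i];
  }
  return List::create(_["edge"] = em, _["edge.length"] = el,
                      _["Nnode"] = (int)tr.adj.size() - n);
}

// [[Rcpp::export]]
List local_tree_cpp(NumericMatrix D, IntegerVector prio) {
  Unrooted tr = nj_agglomerate(as_dmat(D), as_prio(prio));
  std::vector<double> rlen;
  Rooted rt = midpoint_root(tr, &rlen);
  return rooted_to_phylo(rt, rlen);
}

// Sliding-window emergence scan.  `calls` is strains x loci over
// {0, 1, NA}; `chrom` gives an integer chromosome id per locus (loci
// sorted by chromosome, then position); `W` is the window width in
// variants.  Windows slide within chromosomes and are truncated (kept
// at full width, shifted) at chromosome ends.  For every locus the
// window distance matrix is updated incrementally, a neighbor-joining
// tree is built, midpoint-rooted, and the emergence rules are applied
// to the focal variant's calls.
// [[Rcpp::export]]
List emergence_scan_cpp(IntegerMatrix calls, IntegerVector chrom, int W,
                        IntegerVector prio) {
  const int S = calls.nrow();
  const int L = calls.ncol();
  if (S < 3) stop("emergence scan needs at least 3 strains");
  if (W < 4) stop("window width must be at least 4 variants");
  IntegerVector n_events(L), win_lo(L), win_hi(L);
  LogicalVector low_conf(L);
  std::vector<int> pv = as_prio(prio);

  int b0 = 0;
  while (b0 < L) {
    int b1 = b0;
    while (b1 + 1 < L && chrom[b1 + 1] == chrom[b0]) ++b1;
    const int Lc = b1 - b0 + 1;
    const int effW = std::min(W, Lc);
    std::vector<std::vector<double>> D(S, std::vector<double>(S, 0.0));
    int lo = b0, hi = b0 + effW - 1;
    for (int j = lo; j <= hi; ++j) update_pairs(D, calls, j, 1.0);
    for (int i = b0; i <= b1; ++i) {
      int lo_t = i - (effW - 1) / 2;
      if (lo_t < b0) lo_t = b0;
      if (lo_t > b1 - effW + 1) lo_t = b1 - effW + 1;
      while (lo < lo_t) {
        update_pairs(D, calls, lo, -1.0);
        update_pairs(D, calls, hi + 1, 1.0);
        ++lo; ++hi;
      }
      Unrooted tr = nj_agglomerate(D, pv);
      Rooted rt = midpoint_root(tr);
      std::vector<int> st(S);
      for (int a = 0; a < S; ++a) {
        int c = calls(a, i);
        st[a] = (c == NA_INTEGER) ? -9 : c;
      }
      n_events[i] = count_emergences(rt, st);
      win_lo[i] = lo + 1;
      win_hi[i] = hi + 1;
      low_conf[i] = (effW < 4);
    }
    b0 = b1 + 1;
  }
  return List::create(_["n_events"] = n_events, _["window_lo"] = win_lo,
                      _["window_hi"] = win_hi, _["low_confidence"] = low_conf);
}

// Missing-aware pairwise SNP-difference counts for a column range
// [lo, hi] (1-based, inclusive).
// [[Rcpp::export]]
NumericMatrix snp_dist_cpp(IntegerMatrix calls, int lo, int hi) {
  const int S = calls.nrow();
  std::vector<std::vector<double>> D(S, std::vector<double>(S, 0.0));
  for (int j = lo - 1; j <= hi - 1; ++j) update_pairs(D, calls, j, 1.0);
  NumericMatrix out(S, S);
  for (int a = 0; a < S; ++a)
    for (int b = 0; b < S; ++b) out(a, b) = D[a][b];
  return out;
}
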