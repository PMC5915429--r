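#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Edge-disjoint longest paths in a forest with non-negative edge weights.
// P1 is the weight-maximal simple path (double-sweep, valid on trees);
// P_{i+1} is recomputed on the forest left after deleting edges of P_1..P_i.
// Ties are broken by hop count, then by smallest vertex id, so the
// decomposition is deterministic.

struct Sweep {
  std::vector<double> dist;
  std::vector<int> hops, par_v, par_e;
  std::vector<int> comp;  // vertices reached
};

static void sweep_from(int start,
                       const std::vector<std::vector<std::pair<int,int>>> &adj,
                       const std::vector<char> &alive, Sweep &sw) {
  sw.comp.clear();
  std::vector<int> stack;
  stack.push_back(start);
  sw.dist[start] = 0.0; sw.hops[start] = 0;
  sw.par_v[start] = -1; sw.par_e[start] = -1;
  std::vector<char> seen(sw.dist.size(), 0);
  seen[start] = 1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    sw.comp.push_back(v);
    for (auto &ne : adj[v]) {
      int u = ne.first, e = ne.second;
      if (!alive[e] || seen[u]) continue;
      seen[u] = 1;
      sw.par_v[u] = v; sw.par_e[u] = e;
      stack.push_back(u);
    }
  }
  // distances along the unique tree paths, in discovery order is not
  // guaranteed topological for a stack; recompute by walking parents lazily
  for (int v : sw.comp) {
    if (v == start) continue;
    sw.dist[v] = -1.0;
  }
}

// Fill dist/hops for a component given parent pointers (iterative).
static void fill_dists(const Sweep &swc, std::vector<double> &dist,
                       std::vector<int> &hops, const NumericVector &w,
                       int start) {
  for (int v : swc.comp) {
    if (dist[v] >= 0) continue;
    // walk up to a resolved ancestor
    std::vector<int> chain;
    int u = v;
    while (dist[u] < 0) { chain.push_back(u); u = swc.par_v[u]; }
    for (int i = (int)chain.size() - 1; i >= 0; --i) {
      int c = chain[i];
      dist[c] = dist[swc.par_v[c]] + w[swc.par_e[c]];
      hops[c] = hops[swc.par_v[c]] + 1;
    }
  }
  (void)start;
}

static int farthest(const Sweep &sw, const std::vector<double> &dist,
                    const std::vector<int> &hops) {
  int best = sw.comp[0];
  for (int v : sw.comp) {
    if (dist[v] > dist[best] + 1e-12 ||
        (dist[v] > dist[best] - 1e-12 &&
         (hops[v] > hops[best] ||
          (hops[v] == hops[best] && v < best)))) {
      best = v;
    }
  }
  return best;
}

// [[Rcpp::export]]
List k_longest_paths_cpp(int nv, IntegerMatrix edges, NumericVector w,
                         int npaths) {
  const int ne = edges.nrow();
  std::vector<std::vector<std::pair<int,int>>> adj(nv);
  for (int e = 0; e < ne; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    adj[a].push_back({b, e});
    adj[b].push_back({a, e});
  }
  for (int v = 0; v < nv; ++v) std::sort(adj[v].begin(), adj[v].end());
  std::vector<char> alive(ne, 1);
  int n_alive = ne;
  List out;
  Sweep sw;
  sw.dist.assign(nv, 0); sw.hops.assign(nv, 0);
  sw.par_v.assign(nv, -1); sw.par_e.assign(nv, -1);

  for (int p = 0; p < npaths && n_alive > 0; ++p) {
    // best path over all components of the remaining forest
    double best_w = -1.0; int best_hops = -1;
    std::vector<int> best_vpath, best_epath;
    std::vector<char> comp_seen(nv, 0);
    for (int v0 = 0; v0 < nv; ++v0) {
      if (comp_seen[v0]) continue;
      bool has_edge = false;
      for (auto &ne_ : adj[v0]) if (alive[ne_.second]) { has_edge = true; break; }
      if (!has_edge) { comp_seen[v0] = 1; continue; }
      // sweep 1: from v0
      sweep_from(v0, adj, alive, sw);
      for (int v : sw.comp) comp_seen[v] = 1;
      std::vector<double> d1(nv, -1.0); std::vector<int> h1(nv, 0);
      d1[v0] = 0;
      Sweep sw1 = sw;
      fill_dists(sw1, d1, h1, w, v0);
      int u = farthest(sw1, d1, h1);
      // sweep 2: from u, parents give the path
      sweep_from(u, adj, alive, sw);
      std::vector<double> d2(nv, -1.0); std::vector<int> h2(nv, 0);
      d2[u] = 0;
      fill_dists(sw, d2, h2, w, u);
      int vend = farthest(sw, d2, h2);
      double pw = d2[vend]; int ph = h2[vend];
      if (pw > best_w + 1e-12 ||
          (pw > best_w - 1e-12 && ph > best_hops)) {
        best_w = pw; best_hops = ph;
        best_vpath.clear(); best_epath.clear();
        int x = vend;
        while (x != -1) {
          best_vpath.push_back(x);
          if (sw.par_e[x] != -1) best_epath.push_back(sw.par_e[x]);
          x = sw.par_v[x];
        }
        std::reverse(best_vpath.begin(), best_vpath.end());
        std::reverse(best_epath.begin(), best_epath.end());
      }
    }
    if (best_hops < 1) break;  // no component with an edge left
    if (best_vpath.front() > best_vpath.back()) {
      std::reverse(best_vpath.begin(), best_vpath.end());
      std::reverse(best_epath.begin(), best_epath.end());
    }
    for (int e : best_epath) { alive[e] = 0; --n_alive; }
    IntegerVector vp(best_vpath.size()), ep(best_epath.size());
    for (size_t i = 0; i < best_vpath.size(); ++i) vp[i] = best_vpath[i] + 1;
    for (size_t i = 0; i < best_epath.size(); ++i) ep[i] = best_epath[i] + 1;
    out.push_back(List::create(Named("vertices") = vp,
                               Named("edges") = ep,
                               Named("weight") = best_w));
  }
  return out;
}
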