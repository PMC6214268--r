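#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// Compressed adjacency with parallel edge ids, built from a 1-based m x 2
// edge matrix over n nodes (simple undirected graph, already validated in R).
struct Adj {
  int n;
  int m;
  std::vector<int> off;  // size n + 1
  std::vector<int> nbr;  // size 2m
  std::vector<int> eid;  // size 2m
};

static Adj build_adj(const IntegerMatrix &edges, int n) {
  Adj a;
  a.n = n;
  a.m = edges.nrow();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < a.m; ++e) {
    deg[edges(e, 0) - 1]++;
    deg[edges(e, 1) - 1]++;
  }
  a.off.assign(n + 1, 0);
  for (int v = 0; v < n; ++v) a.off[v + 1] = a.off[v] + deg[v];
  a.nbr.assign(2 * (size_t)a.m, 0);
  a.eid.assign(2 * (size_t)a.m, 0);
  std::vector<int> pos(a.off.begin(), a.off.end() - 1);
  for (int e = 0; e < a.m; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    a.nbr[pos[u]] = v; a.eid[pos[u]] = e; pos[u]++;
    a.nbr[pos[v]] = u; a.eid[pos[v]] = e; pos[v]++;
  }
  return a;
}

// Removal order by repeated deletion of the minimum-degree node, ties broken
// by smallest node index. An ordered set keyed by (current degree, index)
// makes the tie-break exact and the output deterministic.
static void sl_order(const Adj &a, std::vector<int> &order,
                     std::vector<int> &rank, int &degeneracy) {
  int n = a.n;
  std::vector<int> deg(n);
  for (int v = 0; v < n; ++v) deg[v] = a.off[v + 1] - a.off[v];
  std::set<std::pair<int, int> > s;
  for (int v = 0; v < n; ++v) s.insert(std::make_pair(deg[v], v));
  std::vector<char> alive(n, 1);
  order.resize(n);
  rank.resize(n);
  degeneracy = 0;
  for (int i = 0; i < n; ++i) {
    std::pair<int, int> mn = *s.begin();
    s.erase(s.begin());
    int v = mn.second;
    if (mn.first > degeneracy) degeneracy = mn.first;
    order[i] = v;
    rank[v] = i;
    alive[v] = 0;
    for (int p = a.off[v]; p < a.off[v + 1]; ++p) {
      int w = a.nbr[p];
      if (!alive[w]) continue;
      s.erase(std::make_pair(deg[w], w));
      deg[w]--;
      s.insert(std::make_pair(deg[w], w));
    }
  }
}

// [[Rcpp::export]]
List sl_order_cpp(IntegerMatrix edges, int n) {
  Adj a = build_adj(edges, n);
  std::vector<int> order, rank;
  int degeneracy = 0;
  sl_order(a, order, rank, degeneracy);
  IntegerVector ord(n), rnk(n);
  for (int i = 0; i < n; ++i) { ord[i] = order[i] + 1; rnk[i] = rank[i] + 1; }
  return List::create(_["order"] = ord, _["rank"] = rnk,
                      _["degeneracy"] = degeneracy);
}

// One scan over the acyclic orientation induced by the removal order:
//  * lists every triangle once (anchored at its earliest node),
//  * lists every K4 once (triangles inside an out-neighborhood),
//  * counts non-induced C4s per node and per edge (anchored at the latest
//    node of the cycle, via common-neighbor multiplicities),
//  * accumulates the triangle-based degree/triangle aggregates the
//    non-induced orbit formulas need.
// All counts are doubles: they stay exact integers below 2^53.
// [[Rcpp::export]]
List quad_scan_cpp(IntegerMatrix edges, int n, bool want_triangles) {
  Adj a = build_adj(edges, n);
  int m = a.m;
  std::vector<int> order, rank;
  int degeneracy = 0;
  sl_order(a, order, rank, degeneracy);

  // oriented out-adjacency: earlier-removed -> later-removed
  std::vector<int> ooff(n + 1, 0), onbr, oeid;
  {
    std::vector<int> cnt(n, 0);
    for (int v = 0; v < n; ++v)
      for (int p = a.off[v]; p < a.off[v + 1]; ++p)
        if (rank[a.nbr[p]] > rank[v]) cnt[v]++;
    for (int v = 0; v < n; ++v) ooff[v + 1] = ooff[v] + cnt[v];
    onbr.resize(ooff[n]); oeid.resize(ooff[n]);
    std::vector<int> pos(n);
    for (int v = 0; v < n; ++v) pos[v] = ooff[v];
    for (int v = 0; v < n; ++v)
      for (int p = a.off[v]; p < a.off[v + 1]; ++p)
        if (rank[a.nbr[p]] > rank[v]) {
          onbr[pos[v]] = a.nbr[p]; oeid[pos[v]] = a.eid[p]; pos[v]++;
        }
  }
  int max_outdeg = 0;
  for (int v = 0; v < n; ++v)
    if (ooff[v + 1] - ooff[v] > max_outdeg) max_outdeg = ooff[v + 1] - ooff[v];

  std::vector<double> deg(n);
  for (int v = 0; v < n; ++v) deg[v] = a.off[v + 1] - a.off[v];

  NumericVector t_node(n), k4_node(n), c4_node(n);
  NumericVector t_edge(m), k4_edge(m), c4_edge(m);
  NumericVector A_node(n), B_node(n);   // sums over triangles at u of
                                        // d(v)+d(w) and t({v,w})
  NumericVector D_edge(m), M_edge(m);   // sums over triangles at e of d(w)
                                        // and t(uw)+t(vw)
  double ops_tri = 0, ops_k4 = 0, ops_c4 = 0;

  std::vector<int> stamp(n, -1), medge(n, -1);
  std::vector<int> stamp2(n, -1), m2edge(n, -1);

  // triangle listing; store (nodes, eids) for the aggregate pass
  std::vector<int> tri_u, tri_v, tri_w, tri_euv, tri_evw, tri_euw;
  for (int u = 0; u < n; ++u) {
    for (int p = ooff[u]; p < ooff[u + 1]; ++p) {
      stamp[onbr[p]] = u; medge[onbr[p]] = oeid[p];
    }
    for (int p = ooff[u]; p < ooff[u + 1]; ++p) {
      int v = onbr[p], euv = oeid[p];
      for (int q = ooff[v]; q < ooff[v + 1]; ++q) {
        ops_tri += 1;
        int w = onbr[q];
        if (stamp[w] == u) {
          int evw = oeid[q], euw = medge[w];
          t_node[u] += 1; t_node[v] += 1; t_node[w] += 1;
          t_edge[euv] += 1; t_edge[evw] += 1; t_edge[euw] += 1;
          tri_u.push_back(u); tri_v.push_back(v); tri_w.push_back(w);
          tri_euv.push_back(euv); tri_evw.push_back(evw); tri_euw.push_back(euw);
        }
      }
    }
  }

  // K4 listing: triangles among common out-neighbors
  int vtick = 0;
  std::vector<int> vstamp(n, -1);
  for (int u = 0; u < n; ++u) {
    for (int p = ooff[u]; p < ooff[u + 1]; ++p) {
      stamp[onbr[p]] = u + n;  // fresh stamp domain for this pass
      medge[onbr[p]] = oeid[p];
    }
    for (int p = ooff[u]; p < ooff[u + 1]; ++p) {
      int v = onbr[p], euv = oeid[p];
      ++vtick;
      for (int q = ooff[v]; q < ooff[v + 1]; ++q) {
        ops_k4 += 1;
        int w = onbr[q];
        if (stamp[w] == u + n) { vstamp[w] = vtick; m2edge[w] = oeid[q]; }
      }
      for (int q = ooff[v]; q < ooff[v + 1]; ++q) {
        int w = onbr[q];
        if (stamp[w] != u + n) continue;
        int evw = oeid[q];
        for (int r = ooff[w]; r < ooff[w + 1]; ++r) {
          ops_k4 += 1;
          int x = onbr[r];
          if (stamp[x] == u + n && vstamp[x] == vtick) {
            int ewx = oeid[r], euw = medge[w], eux = medge[x], evx = m2edge[x];
            k4_node[u] += 1; k4_node[v] += 1; k4_node[w] += 1; k4_node[x] += 1;
            k4_edge[euv] += 1; k4_edge[euw] += 1; k4_edge[eux] += 1;
            k4_edge[evw] += 1; k4_edge[evx] += 1; k4_edge[ewx] += 1;
          }
        }
      }
    }
  }

  // non-induced C4 counting, anchored at the cycle node latest in the order
  {
    std::vector<double> cnt(n, 0.0);
    std::vector<int> touched;
    for (int z = 0; z < n; ++z) {
      touched.clear();
      for (int p = a.off[z]; p < a.off[z + 1]; ++p) {
        ops_c4 += 1;
        int v = a.nbr[p];
        if (rank[v] > rank[z]) continue;  // middles must be earlier than z
        for (int q = a.off[v]; q < a.off[v + 1]; ++q) {
          ops_c4 += 1;
          int w = a.nbr[q];
          if (w == z || rank[w] > rank[z]) continue;
          if (cnt[w] == 0) touched.push_back(w);
          cnt[w] += 1;
        }
      }
      for (int p = a.off[z]; p < a.off[z + 1]; ++p) {
        ops_c4 += 1;
        int v = a.nbr[p];
        if (rank[v] > rank[z]) continue;
        int ezv = a.eid[p];
        for (int q = a.off[v]; q < a.off[v + 1]; ++q) {
          ops_c4 += 1;
          int w = a.nbr[q];
          if (w == z || rank[w] > rank[z]) continue;
          double c = cnt[w];
          if (c >= 2) {
            c4_node[v] += c - 1;
            c4_edge[ezv] += c - 1;
            c4_edge[a.eid[q]] += c - 1;
          }
        }
      }
      for (size_t i = 0; i < touched.size(); ++i) {
        int w = touched[i];
        double c = cnt[w];
        if (c >= 2) {
          double cc = c * (c - 1) / 2;
          c4_node[z] += cc;
          c4_node[w] += cc;
        }
        cnt[w] = 0;
      }
    }
  }

  // aggregate pass over the triangle list (t_edge is complete here)
  size_t ntri = tri_u.size();
  for (size_t i = 0; i < ntri; ++i) {
    int u = tri_u[i], v = tri_v[i], w = tri_w[i];
    int euv = tri_euv[i], evw = tri_evw[i], euw = tri_euw[i];
    A_node[u] += deg[v] + deg[w];
    A_node[v] += deg[u] + deg[w];
    A_node[w] += deg[u] + deg[v];
    B_node[u] += t_edge[evw];
    B_node[v] += t_edge[euw];
    B_node[w] += t_edge[euv];
    D_edge[euv] += deg[w];
    D_edge[euw] += deg[v];
    D_edge[evw] += deg[u];
    M_edge[euv] += t_edge[euw] + t_edge[evw];
    M_edge[euw] += t_edge[euv] + t_edge[evw];
    M_edge[evw] += t_edge[euv] + t_edge[euw];
  }

  IntegerVector ord(n), rnk(n);
  for (int i = 0; i < n; ++i) { ord[i] = order[i] + 1; rnk[i] = rank[i] + 1; }

  List out = List::create(
      _["order"] = ord, _["rank"] = rnk, _["degeneracy"] = degeneracy,
      _["max_outdegree"] = max_outdeg,
      _["t_node"] = t_node, _["k4_node"] = k4_node, _["c4_node"] = c4_node,
      _["t_edge"] = t_edge, _["k4_edge"] = k4_edge, _["c4_edge"] = c4_edge,
      _["A_node"] = A_node, _["B_node"] = B_node,
      _["D_edge"] = D_edge, _["M_edge"] = M_edge,
      _["n_triangles"] = (double)ntri,
      _["ops"] = NumericVector::create(_["triangle"] = ops_tri,
                                       _["k4"] = ops_k4, _["c4"] = ops_c4));
  if (want_triangles) {
    IntegerMatrix tm(ntri, 3);
    for (size_t i = 0; i < ntri; ++i) {
      tm(i, 0) = tri_u[i] + 1; tm(i, 1) = tri_v[i] + 1; tm(i, 2) = tri_w[i] + 1;
    }
    out["triangles"] = tm;
  }
  return out;
}
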