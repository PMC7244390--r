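// Farthest-point sampling on a weighted vertex-adjacency graph.
//
// Maintains, for every vertex, the graph-shortest-path distance to the
// nearest already-selected vertex ("owner"). Each newly selected vertex
// triggers a truncated Dijkstra pass that relaxes only vertices whose
// nearest-selected distance improves, so the total work over all
// selections stays near one full Dijkstra sweep.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
List fps_sample(int n, IntegerMatrix edges, NumericVector weights,
                int k, int start) {
  const double INF = std::numeric_limits<double>::infinity();
  int m = edges.nrow();
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    double w = weights[e];
    adj[a].push_back(std::make_pair(b, w));
    adj[b].push_back(std::make_pair(a, w));
  }
  std::vector<double> dist(n, INF);
  std::vector<int> owner(n, -1);
  IntegerVector selected(k);
  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;

  int cur = start - 1;
  for (int s = 0; s < k; ++s) {
    selected[s] = cur + 1;
    dist[cur] = 0.0;
    owner[cur] = cur;
    pq.push(std::make_pair(0.0, cur));
    while (!pq.empty()) {
      QN top = pq.top(); pq.pop();
      double d = top.first;
      int v = top.second;
      if (d > dist[v]) continue;
      for (size_t i = 0; i < adj[v].size(); ++i) {
        int u = adj[v][i].first;
        double nd = d + adj[v][i].second;
        if (nd < dist[u]) {
          dist[u] = nd;
          owner[u] = owner[v];
          pq.push(std::make_pair(nd, u));
        }
      }
    }
    if (s + 1 < k) {
      // next seed: farthest vertex from the selected set (lowest index wins)
      int best = -1;
      double bd = -1.0;
      for (int v = 0; v < n; ++v) {
        if (dist[v] > bd) { bd = dist[v]; best = v; }
      }
      if (best < 0 || bd == INF) {
        if (bd == INF) stop("graph is disconnected: unreachable vertices remain");
      }
      cur = best;
    }
  }
  IntegerVector owner_out(n);
  for (int v = 0; v < n; ++v) owner_out[v] = owner[v] + 1;
  return List::create(_["selected"] = selected, _["owner"] = owner_out);
}
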