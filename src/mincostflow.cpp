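#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <utility>

// Exact integer min-cost flow by successive shortest paths with Johnson
// potentials. Costs must be integral (they arrive as integer-valued
// doubles; distances are discretized upstream). Negative edge costs are
// allowed as long as the initial graph has no negative cycle -- the
// matching networks are DAGs, so Bellman-Ford initialization terminates.

struct Edge {
  int to;
  long long cap;
  long long cost;
  int rev; // index of reverse edge in g[to]
};

// [[Rcpp::export(name = ".mcf_solve")]]
Rcpp::List mcf_solve(int n_nodes,
                     Rcpp::IntegerVector from,
                     Rcpp::IntegerVector to,
                     Rcpp::NumericVector cap,
                     Rcpp::NumericVector cost,
                     int source, int sink, double flow_req) {
  const int m = from.size();
  std::vector<std::vector<Edge> > g(n_nodes);
  std::vector<std::pair<int, int> > loc(m);
  for (int e = 0; e < m; ++e) {
    int u = from[e], v = to[e];
    long long cp = (long long) cap[e];
    long long cs = (long long) cost[e];
    Edge fwd; fwd.to = v; fwd.cap = cp; fwd.cost = cs; fwd.rev = (int) g[v].size();
    Edge bwd; bwd.to = u; bwd.cap = 0;  bwd.cost = -cs; bwd.rev = (int) g[u].size();
    g[u].push_back(fwd);
    g[v].push_back(bwd);
    loc[e] = std::make_pair(u, (int) g[u].size() - 1);
  }

  const long long INF = std::numeric_limits<long long>::max() / 4;
  std::vector<long long> pot(n_nodes, INF);
  pot[source] = 0;
  for (int iter = 0; iter < n_nodes; ++iter) {
    bool changed = false;
    for (int u = 0; u < n_nodes; ++u) {
      if (pot[u] == INF) continue;
      for (size_t i = 0; i < g[u].size(); ++i) {
        const Edge &e = g[u][i];
        if (e.cap > 0 && pot[u] + e.cost < pot[e.to]) {
          pot[e.to] = pot[u] + e.cost;
          changed = true;
        }
      }
    }
    if (!changed) break;
  }
  for (int u = 0; u < n_nodes; ++u) if (pot[u] == INF) pot[u] = 0;

  long long flow = 0, total_cost = 0;
  const long long req = (long long) flow_req;
  std::vector<long long> dist(n_nodes);
  std::vector<int> pe_node(n_nodes), pe_idx(n_nodes);
  typedef std::pair<long long, int> PQItem;

  while (flow < req) {
    std::fill(dist.begin(), dist.end(), INF);
    dist[source] = 0;
    std::priority_queue<PQItem, std::vector<PQItem>, std::greater<PQItem> > pq;
    pq.push(std::make_pair((long long) 0, source));
    while (!pq.empty()) {
      long long d = pq.top().first;
      int u = pq.top().second;
      pq.pop();
      if (d > dist[u]) continue;
      for (int i = 0; i < (int) g[u].size(); ++i) {
        const Edge &e = g[u][i];
        if (e.cap <= 0) continue;
        long long nd = d + e.cost + pot[u] - pot[e.to];
        if (nd < dist[e.to]) {
          dist[e.to] = nd;
          pe_node[e.to] = u;
          pe_idx[e.to] = i;
          pq.push(std::make_pair(nd, e.to));
        }
      }
    }
    if (dist[sink] >= INF) {
      return Rcpp::List::create(Rcpp::Named("status") = "infeasible");
    }
    for (int u = 0; u < n_nodes; ++u) if (dist[u] < INF) pot[u] += dist[u];
    long long aug = req - flow;
    for (int v = sink; v != source; v = pe_node[v])
      aug = std::min(aug, g[pe_node[v]][pe_idx[v]].cap);
    for (int v = sink; v != source; v = pe_node[v]) {
      Edge &e = g[pe_node[v]][pe_idx[v]];
      e.cap -= aug;
      g[e.to][e.rev].cap += aug;
      total_cost += aug * e.cost;
    }
    flow += aug;
  }

  Rcpp::NumericVector fl(m);
  for (int e = 0; e < m; ++e) {
    const Edge &fe = g[loc[e].first][loc[e].second];
    fl[e] = (double) (((long long) cap[e]) - fe.cap);
  }
  return Rcpp::List::create(
    Rcpp::Named("status") = "optimal",
    Rcpp::Named("flow") = fl,
    Rcpp::Named("total_cost") = (double) total_cost,
    Rcpp::Named("flow_value") = (double) flow);
}
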