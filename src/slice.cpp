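#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <queue>
using namespace Rcpp;

// Greedy connectivity-preserving edge removal: walk the candidate order and
// remove an edge only if its endpoints stay mutually reachable afterwards
// (i.e. the edge is not currently a bridge). Removing an edge can only create
// new bridges, never destroy them, so a single pass over a shuffled order is
// exhaustive for that order.
//
// edges: m x 2 matrix of 1-based node indices; order: 1-based candidate edge
// indices; returns the 1-based indices of removed edges (at most n_remove).
// [[Rcpp::export]]
IntegerVector select_removable_edges(IntegerMatrix edges, int n_nodes,
                                     IntegerVector order, int n_remove) {
  int m = edges.nrow();
  std::vector<std::unordered_multiset<int>> adj(n_nodes);
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    adj[u].insert(v);
    adj[v].insert(u);
  }
  std::vector<int> removed;
  std::vector<int> seen(n_nodes, -1);
  int stamp = 0;
  std::queue<int> q;
  for (int k = 0; k < order.size() && (int)removed.size() < n_remove; ++k) {
    int e = order[k] - 1;
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    adj[u].erase(adj[u].find(v));
    adj[v].erase(adj[v].find(u));
    // BFS u -> v
    ++stamp;
    bool ok = false;
    seen[u] = stamp;
    q.push(u);
    while (!q.empty() && !ok) {
      int x = q.front(); q.pop();
      for (int y : adj[x]) {
        if (seen[y] != stamp) {
          if (y == v) { ok = true; break; }
          seen[y] = stamp;
          q.push(y);
        }
      }
    }
    while (!q.empty()) q.pop();
    if (ok) {
      removed.push_back(e + 1);
    } else {
      adj[u].insert(v);
      adj[v].insert(u);
    }
  }
  return wrap(removed);
}
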