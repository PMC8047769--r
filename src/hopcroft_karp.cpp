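#include <Rcpp.h>
#include <vector>
#include <queue>
#include <functional>
#include <climits>
using namespace Rcpp;

// Hopcroft-Karp maximum bipartite matching.
//
// adj: adjacency lists for the left side, 1-based indices into the right
// side. Returns, for every left node, the matched right node (0 if
// unmatched). Deterministic for a fixed adjacency ordering: augmenting
// paths are explored in list order.
//
// [[Rcpp::export(name = ".hk_match")]]
IntegerVector hk_match(int n_left, int n_right, List adj) {
  std::vector< std::vector<int> > g(n_left);
  for (int u = 0; u < n_left; ++u) {
    IntegerVector nb = adj[u];
    g[u].assign(nb.begin(), nb.end());
  }
  std::vector<int> matchL(n_left + 1, 0), matchR(n_right + 1, 0);
  std::vector<int> dist(n_left + 1, 0);
  const int INF = INT_MAX;

  std::function<bool()> bfs = [&]() -> bool {
    std::queue<int> q;
    for (int u = 1; u <= n_left; ++u) {
      if (matchL[u] == 0) { dist[u] = 0; q.push(u); }
      else dist[u] = INF;
    }
    bool reachable_free = false;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : g[u - 1]) {
        int w = matchR[v];
        if (w == 0) {
          reachable_free = true;
        } else if (dist[w] == INF) {
          dist[w] = dist[u] + 1;
          q.push(w);
        }
      }
    }
    return reachable_free;
  };

  std::function<bool(int)> dfs = [&](int u) -> bool {
    for (int v : g[u - 1]) {
      int w = matchR[v];
      if (w == 0 || (dist[w] == dist[u] + 1 && dfs(w))) {
        matchL[u] = v;
        matchR[v] = u;
        return true;
      }
    }
    dist[u] = INF;
    return false;
  };

  while (bfs()) {
    for (int u = 1; u <= n_left; ++u)
      if (matchL[u] == 0) dfs(u);
  }

  IntegerVector out(n_left);
  for (int u = 1; u <= n_left; ++u) out[u - 1] = matchL[u];
  return out;
}
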