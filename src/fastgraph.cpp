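// Fast graph primitives for the Monte Carlo hot loop: all-pairs topological
// distances (BFS), connected components, cycle-bond detection (bridge
// finding) and shortest-cycle ring perception.  Graphs are tiny (tens of
// atoms), so simple O(n*m) algorithms are ideal.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

static std::vector<std::vector<std::pair<int,int> > >
adjacency(int n, const IntegerVector& bi, const IntegerVector& bj) {
  std::vector<std::vector<std::pair<int,int> > > adj(n);
  for (int k = 0; k < bi.size(); ++k) {
    int a = bi[k] - 1, b = bj[k] - 1;
    adj[a].push_back(std::make_pair(b, k));
    adj[b].push_back(std::make_pair(a, k));
  }
  return adj;
}

// [[Rcpp::export]]
IntegerMatrix cpp_dist(int n, IntegerVector bi, IntegerVector bj) {
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), NA_INTEGER);
  std::vector<std::vector<std::pair<int,int> > > adj = adjacency(n, bi, bj);
  std::vector<int> dist(n);
  std::vector<int> queue_(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    queue_[tail++] = s; dist[s] = 0;
    while (head < tail) {
      int v = queue_[head++];
      for (size_t t = 0; t < adj[v].size(); ++t) {
        int w = adj[v][t].first;
        if (dist[w] < 0) { dist[w] = dist[v] + 1; queue_[tail++] = w; }
      }
    }
    for (int v = 0; v < n; ++v) if (dist[v] >= 0) D(s, v) = dist[v];
  }
  return D;
}

// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerVector bi, IntegerVector bj) {
  IntegerVector comp(n, 0);
  std::vector<std::vector<std::pair<int,int> > > adj = adjacency(n, bi, bj);
  std::vector<int> stack;
  int cid = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s]) continue;
    ++cid;
    stack.push_back(s); comp[s] = cid;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      for (size_t t = 0; t < adj[v].size(); ++t) {
        int w = adj[v][t].first;
        if (!comp[w]) { comp[w] = cid; stack.push_back(w); }
      }
    }
  }
  return comp;
}

// cycle bonds = non-bridges (recursive lowlink on tiny graphs)
static void bridge_dfs(int v, int parent_edge,
                       const std::vector<std::vector<std::pair<int,int> > >& adj,
                       std::vector<int>& disc, std::vector<int>& low,
                       std::vector<bool>& bridge, int& timer) {
  disc[v] = low[v] = ++timer;
  for (size_t t = 0; t < adj[v].size(); ++t) {
    int w = adj[v][t].first, k = adj[v][t].second;
    if (k == parent_edge) continue;
    if (disc[w]) {
      low[v] = std::min(low[v], disc[w]);
    } else {
      bridge_dfs(w, k, adj, disc, low, bridge, timer);
      low[v] = std::min(low[v], low[w]);
      if (low[w] > disc[v]) bridge[k] = true;
    }
  }
}

// [[Rcpp::export]]
LogicalVector cpp_ring_bonds(int n, IntegerVector bi, IntegerVector bj) {
  int m = bi.size();
  std::vector<std::vector<std::pair<int,int> > > adj = adjacency(n, bi, bj);
  std::vector<int> disc(n, 0), low(n, 0);
  std::vector<bool> bridge(m, false);
  int timer = 0;
  for (int s = 0; s < n; ++s)
    if (!disc[s]) bridge_dfs(s, -1, adj, disc, low, bridge, timer);
  LogicalVector out(m);
  for (int k = 0; k < m; ++k) out[k] = !bridge[k];
  return out;
}

// shortest cycle through every non-tree edge, deduplicated by atom set
// [[Rcpp::export]]
List cpp_rings(int n, IntegerVector bi, IntegerVector bj, int maxsize) {
  int m = bi.size();
  std::vector<std::vector<std::pair<int,int> > > adj = adjacency(n, bi, bj);
  // BFS spanning forest
  std::vector<bool> intree(m, false), seen(n, false);
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    if (seen[s]) continue;
    seen[s] = true; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (size_t t = 0; t < adj[v].size(); ++t) {
        int w = adj[v][t].first;
        if (!seen[w]) { seen[w] = true; intree[adj[v][t].second] = true; q.push(w); }
      }
    }
  }
  List rings;
  std::vector<std::vector<int> > keys;
  std::vector<int> prev(n), prevk(n);
  for (int k = 0; k < m; ++k) {
    if (intree[k]) continue;
    int u = bi[k] - 1, v = bj[k] - 1;
    std::fill(prev.begin(), prev.end(), -2);
    prev[u] = -1;
    std::queue<int> bq; bq.push(u);
    bool found = false;
    while (!bq.empty() && !found) {
      int x = bq.front(); bq.pop();
      for (size_t t = 0; t < adj[x].size(); ++t) {
        if (adj[x][t].second == k) continue;
        int w = adj[x][t].first;
        if (prev[w] == -2) {
          prev[w] = x;
          if (w == v) { found = true; break; }
          bq.push(w);
        }
      }
    }
    if (!found) continue;
    std::vector<int> path;
    int cur = v;
    while (cur != -1) { path.push_back(cur + 1); cur = prev[cur]; }
    if ((int)path.size() > maxsize) continue;
    std::vector<int> key(path);
    std::sort(key.begin(), key.end());
    bool dup = false;
    for (size_t i = 0; i < keys.size(); ++i)
      if (keys[i] == key) { dup = true; break; }
    if (dup) continue;
    keys.push_back(key);
    std::reverse(path.begin(), path.end());
    rings.push_back(wrap(path));
  }
  return rings;
}
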