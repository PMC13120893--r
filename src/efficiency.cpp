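// Unweighted shortest-path efficiency metrics on small dense adjacency
// matrices. BFS per source node; unreachable pairs contribute zero
// (infinite-distance convention).
#include <Rcpp.h>
#include <vector>
#include <queue>

// all-pairs BFS distances for a 0/1 adjacency; -1 marks unreachable
static std::vector<std::vector<int> > bfs_all(const std::vector<std::vector<int> >& nbrs) {
  const int p = nbrs.size();
  std::vector<std::vector<int> > d(p, std::vector<int>(p, -1));
  for (int s = 0; s < p; ++s) {
    d[s][s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (size_t a = 0; a < nbrs[u].size(); ++a) {
        int v = nbrs[u][a];
        if (d[s][v] < 0) { d[s][v] = d[s][u] + 1; q.push(v); }
      }
    }
  }
  return d;
}

static std::vector<std::vector<int> > adj_to_nbrs(const Rcpp::IntegerMatrix& adj) {
  const int p = adj.nrow();
  std::vector<std::vector<int> > nbrs(p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j && adj(i, j) != 0) nbrs[i].push_back(j);
  return nbrs;
}

// [[Rcpp::export]]
Rcpp::List cpp_efficiency(const Rcpp::IntegerMatrix& adj) {
  const int p = adj.nrow();
  std::vector<std::vector<int> > nbrs = adj_to_nbrs(adj);
  std::vector<std::vector<int> > d = bfs_all(nbrs);

  Rcpp::NumericVector nodal(p), local(p);

  for (int i = 0; i < p; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j)
      if (j != i && d[i][j] > 0) s += 1.0 / d[i][j];
    nodal[i] = (p > 1) ? s / (p - 1) : 0.0;
  }

  for (int i = 0; i < p; ++i) {
    const std::vector<int>& nb = nbrs[i];
    const int m = nb.size();
    if (m < 2) { local[i] = 0.0; continue; }
    // induced subgraph on the neighbours of i (i itself removed)
    std::vector<std::vector<int> > sub(m);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        if (a != b && adj(nb[a], nb[b]) != 0) sub[a].push_back(b);
    std::vector<std::vector<int> > ds = bfs_all(sub);
    double s = 0.0;
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        if (a != b && ds[a][b] > 0) s += 1.0 / ds[a][b];
    local[i] = s / (static_cast<double>(m) * (m - 1));
  }

  return Rcpp::List::create(Rcpp::Named("nodal") = nodal,
                            Rcpp::Named("local") = local);
}
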