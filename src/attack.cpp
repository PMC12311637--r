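#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Mean largest-component size after i = 1..n random node removals,
// averaged over n_iter uniformly random removal orders. Implemented by
// re-adding nodes in reverse order with a union-find, so each iteration
// costs O((n + E) alpha). Uses R's RNG, hence reproducible via set.seed().
// [[Rcpp::export]]
NumericVector attack_sigma_mc(int n, IntegerMatrix edges, int n_iter) {
  int E = edges.nrow();
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < E; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  NumericVector sigma_sum(n);  // sigma_sum[i-1] accumulates sizes after i removals
  std::vector<int> parent(n), sz(n), order(n);
  std::vector<char> active(n);

  for (int it = 0; it < n_iter; ++it) {
    for (int v = 0; v < n; ++v) order[v] = v;
    // Fisher-Yates using R's RNG
    for (int j = n - 1; j >= 1; --j) {
      int k = (int)(unif_rand() * (j + 1));
      if (k > j) k = j;
      std::swap(order[j], order[k]);
    }
    std::fill(active.begin(), active.end(), 0);
    int maxsz = 0;
    // after i removals the survivors are order[i..n-1]; add them back
    // from j = n-1 down to 1, recording the running largest component
    for (int j = n - 1; j >= 1; --j) {
      int v = order[j];
      parent[v] = v;
      sz[v] = 1;
      active[v] = 1;
      int rv = v;
      for (size_t t = 0; t < adj[v].size(); ++t) {
        int u = adj[v][t];
        if (!active[u]) continue;
        int ru = uf_find(parent, u);
        rv = uf_find(parent, rv);
        if (ru != rv) {
          if (sz[ru] < sz[rv]) std::swap(ru, rv);
          parent[rv] = ru;
          sz[ru] += sz[rv];
          rv = ru;
        }
      }
      rv = uf_find(parent, v);
      if (sz[rv] > maxsz) maxsz = sz[rv];
      sigma_sum[j - 1] += maxsz;
    }
    // i = n removals leaves nothing: sigma_sum[n-1] += 0
  }
  for (int i = 0; i < n; ++i) sigma_sum[i] /= n_iter;
  return sigma_sum;
}
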