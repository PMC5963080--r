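#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Random-walk corpus generation over an undirected graph.
//
// adj: list of 1-based sorted integer neighbour vectors, one per node.
// biased = false: first-order uniform walks (DeepWalk style).
// biased = true : second-order walks with unnormalized transition weights
//   1/p back to the previous node, 1 to a neighbour of the previous node,
//   1/q otherwise (node2vec style).
// Exactly walks_per_vertex walks start from every node, in a shuffled start
// order per pass; walks from isolated nodes have length 1.
// [[Rcpp::export]]
List gen_walks_cpp(List adj, int walk_length, int walks_per_vertex,
                   bool biased, double p, double q, int seed) {
  int n = adj.size();
  std::vector<std::vector<int>> A(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    A[i].assign(nb.begin(), nb.end());
    for (int &x : A[i]) --x;               // 0-based
    std::sort(A[i].begin(), A[i].end());
  }
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  List out(n * walks_per_vertex);
  int w = 0;
  std::vector<int> starts(n);
  for (int i = 0; i < n; ++i) starts[i] = i;
  std::vector<double> wt;
  for (int pass = 0; pass < walks_per_vertex; ++pass) {
    std::shuffle(starts.begin(), starts.end(), rng);
    for (int s : starts) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(s);
      int prev = -1, cur = s;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int> &nb = A[cur];
        if (nb.empty()) break;
        int nxt;
        if (!biased || prev < 0) {
          nxt = nb[(int)(unif(rng) * nb.size()) % nb.size()];
        } else {
          const std::vector<int> &pn = A[prev];
          wt.resize(nb.size());
          double tot = 0.0;
          for (size_t j = 0; j < nb.size(); ++j) {
            int x = nb[j];
            double wj;
            if (x == prev) wj = 1.0 / p;
            else if (std::binary_search(pn.begin(), pn.end(), x)) wj = 1.0;
            else wj = 1.0 / q;
            tot += wj;
            wt[j] = tot;
          }
          double r = unif(rng) * tot;
          size_t j = std::lower_bound(wt.begin(), wt.end(), r) - wt.begin();
          if (j >= nb.size()) j = nb.size() - 1;
          nxt = nb[j];
        }
        walk.push_back(nxt);
        prev = cur;
        cur = nxt;
      }
      IntegerVector iw(walk.size());
      for (size_t j = 0; j < walk.size(); ++j) iw[j] = walk[j] + 1;
      out[w++] = iw;
    }
  }
  return out;
}
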