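#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
using namespace Rcpp;

// Skip-gram with negative sampling (word2vec-style) over a walk corpus.
// Single-threaded and fully determined by `seed`. Input vectors ("syn0")
// start uniform in [-0.5/dim, 0.5/dim]; context vectors start at zero;
// negatives are drawn from the unigram distribution raised to 3/4; the
// learning rate decays linearly from `alpha` to alpha/1e4 over all
// target-context pairs. Returns the input vectors, one row per vocabulary id.
//
// walks: list of 1-based integer vectors; vocab: vocabulary size.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List walks, int vocab, int dim, int window,
                             int epochs, int negative, double alpha,
                             int seed) {
  std::vector<std::vector<int>> W(walks.size());
  std::vector<double> cnt(vocab, 0.0);
  long long tokens = 0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    W[i].assign(w.begin(), w.end());
    for (int &x : W[i]) { --x; cnt[x] += 1.0; }
    tokens += W[i].size();
  }
  // unigram^0.75 sampling table
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  double Z = 0.0;
  for (int v = 0; v < vocab; ++v) Z += std::pow(cnt[v], 0.75);
  {
    int v = 0;
    double cum = std::pow(cnt[0], 0.75) / Z;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((double)(i + 1) / table_size > cum && v < vocab - 1) {
        ++v;
        cum += std::pow(cnt[v], 0.75) / Z;
      }
    }
  }
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif(rng) - 0.5) / dim;

  // rough pair budget for the linear learning-rate schedule
  double total_pairs = (double)epochs * (double)tokens * 2.0 * window;
  double done = 0.0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t wi = 0; wi < W.size(); ++wi) {
      const std::vector<int> &walk = W[wi];
      int L = (int)walk.size();
      for (int t = 0; t < L; ++t) {
        int target = walk[t];
        int lo = std::max(0, t - window), hi = std::min(L - 1, t + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == t) continue;
          double lr = alpha * (1.0 - done / (total_pairs + 1.0));
          if (lr < alpha * 1e-4) lr = alpha * 1e-4;
          done += 1.0;
          int ctx = walk[j];
          double *v_t = &syn0[(size_t)target * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int out;
            double label;
            if (k == 0) { out = ctx; label = 1.0; }
            else {
              out = table[(int)(unif(rng) * table_size) % table_size];
              if (out == ctx) continue;
              label = 0.0;
            }
            double *v_o = &syn1[(size_t)out * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_t[d] * v_o[d];
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - pred) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_o[d];
              v_o[d] += g * v_t[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_t[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
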