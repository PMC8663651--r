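// Skip-gram with negative sampling, single-threaded and fully determined by
// the seed. Follows the classic word2vec training loop: dynamic window
// shrink, unigram^0.75 negative-sampling table, linear learning-rate decay.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double fast_sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// word2vec's 64-bit LCG
static inline uint64_t next_rand(uint64_t &state) {
  state = state * 25214903917ULL + 11ULL;
  return state;
}

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, IntegerVector vocab_counts,
                             int dim, int window, int negative, int epochs,
                             double alpha, double min_alpha, int seed) {
  const int V = vocab_counts.size();
  const int table_size = 100000;

  // negative-sampling table: counts^0.75
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int i = 0; i < V; ++i) total += std::pow((double)vocab_counts[i], 0.75);
    int i = 0;
    double cum = std::pow((double)vocab_counts[0], 0.75) / total;
    for (int a = 0; a < table_size; ++a) {
      table[a] = i;
      if ((double)a / table_size > cum && i < V - 1) {
        ++i;
        cum += std::pow((double)vocab_counts[i], 0.75) / total;
      }
    }
  }

  uint64_t rng = (uint64_t)seed;
  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t a = 0; a < syn0.size(); ++a) {
    syn0[a] = (((next_rand(rng) >> 16) % 65536) / 65536.0 - 0.5) / dim;
  }

  // pre-count corpus words for the learning-rate schedule
  long long total_words = 0;
  const int S = sentences.size();
  for (int s = 0; s < S; ++s) total_words += ((IntegerVector)sentences[s]).size();
  long long train_total = (long long)epochs * std::max(1LL, total_words);
  long long processed = 0;

  std::vector<double> neu1e(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      IntegerVector sen = sentences[s];
      const int n = sen.size();
      for (int pos = 0; pos < n; ++pos) {
        ++processed;
        double lr = alpha - (alpha - min_alpha) * ((double)processed / train_total);
        if (lr < min_alpha) lr = min_alpha;
        const int word = sen[pos]; // center word (output side)
        const int b = (int)(next_rand(rng) >> 16) % window;
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int c = pos + off;
          if (c < 0 || c >= n) continue;
          const int last = sen[c]; // context word (input side)
          double *v_in = &syn0[(size_t)last * dim];
          for (int d = 0; d < dim; ++d) neu1e[d] = 0.0;
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = word; label = 1.0; }
            else {
              target = table[(next_rand(rng) >> 16) % table_size];
              if (target == word) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += v_in[d] * v_out[d];
            const double g = (label - fast_sigmoid(f)) * lr;
            for (int d = 0; d < dim; ++d) {
              neu1e[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += neu1e[d];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  return out;
}
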