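#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Skip-gram with negative sampling (SGNS), single-threaded and fully
// deterministic given `seed`. Follows the reference word2vec training loop:
// dynamic window shrinkage, unigram^0.75 negative-sampling table, linear
// learning-rate decay, tabulated sigmoid.

static const int EXP_TABLE_SIZE = 1000;
static const double MAX_EXP = 6.0;

static inline std::uint64_t next_rand(std::uint64_t &s) {
  s = s * 25214903917ULL + 11ULL;
  return s;
}

// [[Rcpp::export]]
NumericMatrix sgns_train(IntegerVector tokens, IntegerVector sent_len,
                         int vocab_size, NumericVector counts,
                         int dim, int window, int epochs, int negative,
                         double alpha, int seed) {
  const std::size_t n_tok = tokens.size();
  const int n_sent = sent_len.size();

  std::vector<double> exp_table(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double e = std::exp((i / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    exp_table[i] = e / (e + 1.0);
  }

  // negative-sampling table, unigram distribution to the 3/4 power
  const int table_size = 1000000;
  std::vector<int> neg_table(table_size);
  {
    double total = 0.0;
    for (int v = 0; v < vocab_size; ++v) total += std::pow(counts[v], 0.75);
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / total;
    for (int i = 0; i < table_size; ++i) {
      neg_table[i] = v;
      if ((i + 1.0) / table_size > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / total;
      }
    }
  }

  std::uint64_t rng = (std::uint64_t)seed;
  std::vector<double> syn0((std::size_t)vocab_size * dim);
  std::vector<double> syn1((std::size_t)vocab_size * dim, 0.0);
  for (std::size_t i = 0; i < syn0.size(); ++i) {
    next_rand(rng);
    syn0[i] = (((rng >> 16) & 0xFFFF) / 65536.0 - 0.5) / dim;
  }

  const double total_words = (double)n_tok * epochs;
  double processed = 0.0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    std::size_t offset = 0;
    for (int s = 0; s < n_sent; ++s) {
      const int len = sent_len[s];
      for (int pos = 0; pos < len; ++pos) {
        const int center = tokens[offset + pos];
        double lr = alpha * (1.0 - processed / (total_words + 1.0));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        processed += 1.0;
        const int b = (int)(next_rand(rng) % (std::uint64_t)window);
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          const int cpos = pos - window + a;
          if (cpos < 0 || cpos >= len) continue;
          const int context = tokens[offset + cpos];
          double *v_in = &syn0[(std::size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d2 = 0; d2 < negative + 1; ++d2) {
            int target;
            double label;
            if (d2 == 0) {
              target = center;
              label = 1.0;
            } else {
              target = neg_table[(next_rand(rng) >> 16) % table_size];
              if (target == center) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(std::size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            double g;
            if (f > MAX_EXP) g = (label - 1.0) * lr;
            else if (f < -MAX_EXP) g = label * lr;
            else {
              int idx = (int)((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0));
              g = (label - exp_table[idx]) * lr;
            }
            for (int k = 0; k < dim; ++k) grad[k] += g * v_out[k];
            for (int k = 0; k < dim; ++k) v_out[k] += g * v_in[k];
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
      offset += len;
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[(std::size_t)v * dim + k];
  return out;
}
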