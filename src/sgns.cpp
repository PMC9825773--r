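#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Skip-gram with negative sampling over a walk corpus, in the word2vec
// tradition: dynamic (uniformly shrunk) context window, unigram^0.75
// negative-sampling table, linear learning-rate decay, single thread.
// Deterministic for a fixed seed.

static const int NEG_TABLE_BITS = 20;
static const int NEG_TABLE_SIZE = 1 << NEG_TABLE_BITS;

// [[Rcpp::export(name = ".cpp_train_sgns")]]
NumericMatrix cpp_train_sgns(List sentences, int vocab_size, int dim,
                             int window, int negative, int epochs,
                             double alpha, double min_alpha, double seed) {
  // flatten corpus to 0-based tokens with sentence boundaries
  std::vector<std::vector<int>> corpus;
  corpus.reserve(sentences.size());
  long long total_tokens = 0;
  std::vector<long long> freq(vocab_size, 0);
  for (int i = 0; i < sentences.size(); ++i) {
    IntegerVector s = sentences[i];
    std::vector<int> sent;
    sent.reserve(s.size());
    for (int j = 0; j < s.size(); ++j) {
      int w = s[j] - 1;
      if (w < 0 || w >= vocab_size) stop("token index out of range");
      sent.push_back(w);
      ++freq[w];
    }
    total_tokens += sent.size();
    corpus.push_back(std::move(sent));
  }
  if (total_tokens == 0) stop("empty walk corpus");

  // negative-sampling table proportional to freq^0.75
  std::vector<int> neg_table(NEG_TABLE_SIZE);
  double z = 0.0;
  for (int w = 0; w < vocab_size; ++w) z += std::pow((double)freq[w], 0.75);
  {
    int w = 0;
    double cum = std::pow((double)freq[0], 0.75) / z;
    for (int i = 0; i < NEG_TABLE_SIZE; ++i) {
      neg_table[i] = w;
      if ((double)(i + 1) / NEG_TABLE_SIZE > cum && w < vocab_size - 1) {
        ++w;
        cum += std::pow((double)freq[w], 0.75) / z;
      }
    }
  }

  XRng rng(static_cast<uint64_t>(seed));
  std::vector<float> syn0((size_t)vocab_size * dim);
  std::vector<float> syn1((size_t)vocab_size * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((rng.unif() - 0.5) / dim);

  std::vector<float> grad(dim);
  const long long sched = total_tokens * (long long)epochs;
  long long done = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t si = 0; si < corpus.size(); ++si) {
      const std::vector<int> &sent = corpus[si];
      int n = (int)sent.size();
      for (int pos = 0; pos < n; ++pos, ++done) {
        double lr = alpha + (min_alpha - alpha) * ((double)done / sched);
        int center = sent[pos];
        int b = (int)rng.below(window);  // shrink window uniformly
        int lo = pos - window + b, hi = pos + window - b;
        if (lo < 0) lo = 0;
        if (hi > n - 1) hi = n - 1;
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          int ctx = sent[j];
          float *v_in = &syn0[(size_t)ctx * dim];
          std::fill(grad.begin(), grad.end(), 0.0f);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = center;
              label = 1.0;
            } else {
              target = neg_table[rng.below(NEG_TABLE_SIZE)];
              if (target == center) continue;
              label = 0.0;
            }
            float *v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += (double)v_in[d] * v_out[d];
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - pred) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += (float)(g * v_out[d]);
              v_out[d] += (float)(g * v_in[d]);
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int w = 0; w < vocab_size; ++w)
    for (int d = 0; d < dim; ++d)
      out(w, d) = syn0[(size_t)w * dim + d];
  return out;
}
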