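#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// doc, word: 0-based token streams (one entry per token occurrence).
// Draws go through R's RNG (unif_rand) so set.seed() on the R side makes
// the whole fit deterministic.
//
// [[Rcpp::export]]
List lda_gibbs(IntegerVector doc, IntegerVector word, int n_docs, int n_vocab,
               int n_topics, double alpha, double eta, int n_iter) {
  const int n_tok = doc.size();
  IntegerMatrix ndk(n_docs, n_topics);   // doc-topic counts
  IntegerMatrix nkw(n_topics, n_vocab);  // topic-word counts
  IntegerVector nk(n_topics);            // topic totals
  IntegerVector z(n_tok);

  RNGScope scope;

  // random initial assignment
  for (int t = 0; t < n_tok; ++t) {
    int k = (int)(unif_rand() * n_topics);
    if (k == n_topics) k = n_topics - 1;
    z[t] = k;
    ndk(doc[t], k) += 1;
    nkw(k, word[t]) += 1;
    nk[k] += 1;
  }

  std::vector<double> p(n_topics);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int t = 0; t < n_tok; ++t) {
      const int d = doc[t], w = word[t];
      int k = z[t];
      ndk(d, k) -= 1; nkw(k, w) -= 1; nk[k] -= 1;

      double total = 0.0;
      for (int j = 0; j < n_topics; ++j) {
        p[j] = (ndk(d, j) + alpha) * (nkw(j, w) + eta) / (nk[j] + n_vocab * eta);
        total += p[j];
      }
      double u = unif_rand() * total;
      double cum = 0.0;
      int knew = n_topics - 1;
      for (int j = 0; j < n_topics; ++j) {
        cum += p[j];
        if (u <= cum) { knew = j; break; }
      }
      z[t] = knew;
      ndk(d, knew) += 1; nkw(knew, w) += 1; nk[knew] += 1;
    }
  }

  return List::create(_["ndk"] = ndk, _["nkw"] = nkw, _["z"] = z);
}
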