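// Skip-gram with negative sampling over the 4-token nucleotide
// vocabulary. Tokens arrive 0-based (A=0, C=1, G=2, U=3). SGD visits
// (centre, context) pairs in deterministic order (sentence, position,
// offset ascending); negatives come from the unigram^(3/4) noise
// distribution via a private mt19937, so training is bit-reproducible
// given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

static const int VOCAB = 4;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// [[Rcpp::export]]
Rcpp::List cpp_skipgram_train(Rcpp::List sentences, int dim, int window,
                              int epochs, int k_neg, double lr0,
                              Rcpp::NumericVector counts, int seed) {
  const int S = sentences.size();
  std::vector<std::vector<int>> corpus(S);
  long long total_pairs = 0;
  for (int s = 0; s < S; ++s) {
    Rcpp::IntegerVector sv = sentences[s];
    corpus[s].assign(sv.begin(), sv.end());
    const int n = corpus[s].size();
    for (int i = 0; i < n; ++i) {
      int lo = std::max(0, i - window), hi = std::min(n - 1, i + window);
      total_pairs += (hi - lo); // excludes the centre itself
    }
  }
  if (total_pairs == 0) Rcpp::stop("corpus yields no skip-gram pairs");

  // noise distribution: unigram frequency ^ 3/4
  arma::vec noise(VOCAB, arma::fill::zeros);
  for (int w = 0; w < VOCAB; ++w)
    noise[w] = counts[w] > 0 ? std::pow((double)counts[w], 0.75) : 0.0;
  noise /= arma::accu(noise);
  arma::vec cdf = arma::cumsum(noise);

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  std::uniform_real_distribution<double> init(-0.5 / dim, 0.5 / dim);

  arma::mat Win(VOCAB, dim), Wout(VOCAB, dim, arma::fill::zeros);
  for (int w = 0; w < VOCAB; ++w)
    for (int j = 0; j < dim; ++j) Win(w, j) = init(rng);

  auto draw_noise = [&](int exclude) {
    for (;;) {
      double u = unif01(rng);
      int w = 0;
      while (w < VOCAB - 1 && u > cdf[w]) ++w;
      if (w != exclude && noise[w] > 0) return w;
    }
  };

  const double T = (double)total_pairs * epochs;
  long long t = 0;
  arma::vec epoch_loss(epochs, arma::fill::zeros);
  arma::rowvec gcen(dim);

  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0.0;
    long long npairs = 0;
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& sen = corpus[s];
      const int n = sen.size();
      for (int i = 0; i < n; ++i) {
        for (int m = -window; m <= window; ++m) {
          if (m == 0) continue;
          int j = i + m;
          if (j < 0 || j >= n) continue;
          const int cen = sen[i], ctx = sen[j];
          const double lr = lr0 * std::max(1.0 - (double)t / T, 1e-4);
          ++t;
          ++npairs;
          gcen.zeros();
          double s_pos = sigmoid(arma::dot(Wout.row(ctx), Win.row(cen)));
          double loss = -std::log(std::max(s_pos, 1e-300));
          gcen += (s_pos - 1.0) * Wout.row(ctx);
          Wout.row(ctx) -= lr * (s_pos - 1.0) * Win.row(cen);
          for (int k = 0; k < k_neg; ++k) {
            int neg = draw_noise(ctx);
            double s_neg = sigmoid(arma::dot(Wout.row(neg), Win.row(cen)));
            loss -= std::log(std::max(1.0 - s_neg, 1e-300));
            gcen += s_neg * Wout.row(neg);
            Wout.row(neg) -= lr * s_neg * Win.row(cen);
          }
          Win.row(cen) -= lr * gcen;
          loss_sum += loss;
        }
      }
    }
    epoch_loss[e] = loss_sum / (double)npairs;
  }

  return Rcpp::List::create(
      Rcpp::Named("input_vectors") = Win,
      Rcpp::Named("output_vectors") = Wout,
      Rcpp::Named("epoch_loss") = epoch_loss);
}
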