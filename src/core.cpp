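#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Sample a nucleotide sequence (codes 0..3 = A,C,G,T) from an order-2 Markov
// chain. `trans` is 16 x 4 row-stochastic: row index = 4*prev2 + prev1,
// i.e. the state is the preceding dinucleotide. `init` is the initial
// dinucleotide, length 2. Uses R's RNG so set.seed() governs the draw.
// [[Rcpp::export]]
IntegerVector cpp_markov_seq(int n, NumericMatrix trans, IntegerVector init) {
  if (n < 2) stop("sequence length must be >= 2");
  IntegerVector out(n);
  out[0] = init[0];
  out[1] = init[1];
  for (int i = 2; i < n; ++i) {
    int state = 4 * out[i - 2] + out[i - 1];
    double u = unif_rand();
    double acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(state, j);
      if (u <= acc) { b = j; break; }
    }
    out[i] = b;
  }
  return out;
}

static arma::mat squared_dist(const arma::mat& X) {
  arma::colvec s = arma::sum(arma::square(X), 1);
  arma::mat D = -2.0 * (X * X.t());
  D.each_col() += s;
  D.each_row() += s.t();
  D.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return D;
}

// Row-wise binary search for the Gaussian bandwidths that hit the target
// perplexity, then symmetrisation: the standard high-dimensional affinity
// construction of SNE.
static arma::mat input_affinities(const arma::mat& X, double perplexity) {
  const int n = X.n_rows;
  arma::mat D = squared_dist(X);
  arma::mat P(n, n, arma::fill::zeros);
  const double logU = std::log(perplexity);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -arma::datum::inf, betamax = arma::datum::inf;
    double sumP = 0.0;
    for (int iter = 0; iter < 100; ++iter) {
      sumP = 0.0;
      double sumDP = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { P(i, j) = 0.0; continue; }
        double p = std::exp(-beta * D(i, j));
        P(i, j) = p;
        sumP += p;
        sumDP += D(i, j) * p;
      }
      if (sumP <= 0) sumP = 1e-300;
      double H = std::log(sumP) + beta * sumDP / sumP;
      double diff = H - logU;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) {
        betamin = beta;
        beta = std::isinf(betamax) ? beta * 2.0 : (beta + betamax) / 2.0;
      } else {
        betamax = beta;
        beta = std::isinf(betamin) ? beta / 2.0 : (beta + betamin) / 2.0;
      }
    }
    for (int j = 0; j < n; ++j) P(i, j) /= sumP;
  }
  P = (P + P.t()) / (2.0 * n);
  P.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  return P;
}

// t-distributed stochastic neighbour embedding to 2-D with the exact
// O(n^2) gradient (the theta -> 0 limit of the Barnes-Hut approximation),
// early exaggeration and adaptive gains. Initial coordinates come from
// R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_tsne(NumericMatrix Xin, double perplexity, int max_iter,
                       double eta, double exaggeration, int stop_lying_iter,
                       int momentum_switch_iter) {
  arma::mat X(Xin.begin(), Xin.nrow(), Xin.ncol(), false);
  const int n = X.n_rows;
  if (n - 1 < 3 * perplexity) stop("too few points for the requested perplexity");
  arma::mat P = input_affinities(X, perplexity);
  arma::mat Pex = P * exaggeration;

  arma::mat Y(n, 2), dY(n, 2, arma::fill::zeros), uY(n, 2, arma::fill::zeros);
  arma::mat gains(n, 2, arma::fill::ones);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 2; ++d) Y(i, d) = norm_rand() * 1e-4;

  arma::mat num(n, n);
  for (int iter = 0; iter < max_iter; ++iter) {
    const arma::mat& Pcur = (iter < stop_lying_iter) ? Pex : P;
    // Student-t kernel in the embedding
    arma::colvec s = arma::sum(arma::square(Y), 1);
    num = -2.0 * (Y * Y.t());
    num.each_col() += s;
    num.each_row() += s.t();
    num.transform([](double v) { return 1.0 / (1.0 + (v < 0 ? 0.0 : v)); });
    num.diag().zeros();
    double sumQ = arma::accu(num);
    if (sumQ < 1e-300) sumQ = 1e-300;

    dY.zeros();
    for (int i = 0; i < n; ++i) {
      double gx = 0.0, gy = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double mult = (Pcur(i, j) - num(i, j) / sumQ) * num(i, j);
        gx += mult * (Y(i, 0) - Y(j, 0));
        gy += mult * (Y(i, 1) - Y(j, 1));
      }
      dY(i, 0) = 4.0 * gx;
      dY(i, 1) = 4.0 * gy;
    }

    double momentum = (iter < momentum_switch_iter) ? 0.5 : 0.8;
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 2; ++d) {
        gains(i, d) = (std::signbit(dY(i, d)) != std::signbit(uY(i, d)))
                          ? gains(i, d) + 0.2
                          : gains(i, d) * 0.8;
        if (gains(i, d) < 0.01) gains(i, d) = 0.01;
        uY(i, d) = momentum * uY(i, d) - eta * gains(i, d) * dY(i, d);
        Y(i, d) += uY(i, d);
      }
    }
    Y.each_row() -= arma::mean(Y, 0);
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return wrap(Y);
}
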