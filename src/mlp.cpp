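// Two-hidden-layer ReLU classifier trained with Adam on softmax
// cross-entropy. Deterministic: weight init and batch shuffling use a
// private mt19937 stream, never R's RNG.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat init_weights(int r, int c, std::mt19937& gen) {
  std::normal_distribution<double> norm(0.0, 1.0);
  mat W(r, c);
  const double sd = std::sqrt(2.0 / r);  // He init, fan-in = rows
  for (uword j = 0; j < W.n_cols; ++j)
    for (uword i = 0; i < W.n_rows; ++i)
      W(i, j) = norm(gen) * sd;
  return W;
}

struct Adam {
  mat m, v;
  Adam(int r, int c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& W, const mat& g, double lr, int t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    mat mh = m / (1 - std::pow(b1, t));
    mat vh = v / (1 - std::pow(b2, t));
    W -= lr * mh / (sqrt(vh) + eps);
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_mlp_train(const arma::mat& X, const arma::ivec& y,
                         int n_classes, int h1, int h2, int epochs,
                         int batch_size, double lr, int seed) {
  const int n = X.n_rows, d = X.n_cols;
  if (n == 0 || n_classes < 2) Rcpp::stop("need data and >= 2 classes");
  std::mt19937 gen(static_cast<uint32_t>(seed));

  mat W1 = init_weights(d, h1, gen);
  mat W2 = init_weights(h1, h2, gen);
  mat W3 = init_weights(h2, n_classes, gen);
  rowvec b1(h1, fill::zeros), b2v(h2, fill::zeros), b3(n_classes, fill::zeros);

  Adam aW1(d, h1), aW2(h1, h2), aW3(h2, n_classes);
  Adam ab1(1, h1), ab2(1, h2), ab3(1, n_classes);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int t = 0;
  double last_loss = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), gen);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      const int B = stop - start;
      uvec rows(B);
      for (int i = 0; i < B; ++i) rows[i] = idx[start + i];
      mat Xb = X.rows(rows);

      mat Z1 = Xb * W1; Z1.each_row() += b1;
      mat A1 = clamp(Z1, 0.0, datum::inf);
      mat Z2 = A1 * W2; Z2.each_row() += b2v;
      mat A2 = clamp(Z2, 0.0, datum::inf);
      mat Z3 = A2 * W3; Z3.each_row() += b3;

      // row-wise softmax with max-shift
      vec mx = max(Z3, 1);
      Z3.each_col() -= mx;
      mat P = exp(Z3);
      vec Zs = sum(P, 1);
      P.each_col() /= Zs;

      double loss = 0.0;
      mat G3 = P;
      for (int i = 0; i < B; ++i) {
        const int cls = y[rows[i]];
        loss -= std::log(std::max(P(i, cls), 1e-300));
        G3(i, cls) -= 1.0;
      }
      ep_loss += loss / B;
      ++n_batches;
      G3 /= B;

      mat gW3 = A2.t() * G3;
      rowvec gb3 = sum(G3, 0);
      mat G2 = (G3 * W3.t()) % conv_to<mat>::from(Z2 > 0);
      mat gW2 = A1.t() * G2;
      rowvec gb2 = sum(G2, 0);
      mat G1 = (G2 * W2.t()) % conv_to<mat>::from(Z1 > 0);
      mat gW1 = Xb.t() * G1;
      rowvec gb1 = sum(G1, 0);

      ++t;
      aW1.step(W1, gW1, lr, t); aW2.step(W2, gW2, lr, t); aW3.step(W3, gW3, lr, t);
      mat b1m(b1), b2m(b2v), b3m(b3);
      ab1.step(b1m, gb1, lr, t); ab2.step(b2m, gb2, lr, t); ab3.step(b3m, gb3, lr, t);
      b1 = b1m.row(0); b2v = b2m.row(0); b3 = b3m.row(0);
    }
    last_loss = ep_loss / n_batches;
  }

  return Rcpp::List::create(
    Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
    Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2v,
    Rcpp::Named("W3") = W3, Rcpp::Named("b3") = b3,
    Rcpp::Named("final_loss") = last_loss);
}

// [[Rcpp::export]]
arma::mat cpp_mlp_predict(const arma::mat& X, const arma::mat& W1,
                          const arma::rowvec& b1, const arma::mat& W2,
                          const arma::rowvec& b2, const arma::mat& W3,
                          const arma::rowvec& b3) {
  mat Z1 = X * W1; Z1.each_row() += b1;
  mat A1 = clamp(Z1, 0.0, datum::inf);
  mat Z2 = A1 * W2; Z2.each_row() += b2;
  mat A2 = clamp(Z2, 0.0, datum::inf);
  mat Z3 = A2 * W3; Z3.each_row() += b3;
  vec mx = max(Z3, 1);
  Z3.each_col() -= mx;
  mat P = exp(Z3);
  vec s = sum(P, 1);
  P.each_col() /= s;
  return P;
}
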