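// Hot inner loops of the 1-D convolution ('same' padding, stride 1).
// Feature maps are (B*T) x C matrices with sample-major rows; W holds k
// stacked (Cin x Cout) tap blocks.  Everything else in the network stays
// in R; only these row-shifted GEMM accumulations need compiled code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& X, const arma::mat& W,
                         const arma::vec& b, int k, int B, int T) {
  const int Cin = X.n_cols;
  const int left = (k - 1) / 2;
  mat Y(X.n_rows, W.n_cols);
  Y.each_row() = b.t();
  for (int j = 0; j < k; ++j) {
    const int o = j - left;
    const int lo = std::max(0, -o), hi = std::min(T - 1, T - 1 - o);
    if (lo > hi) continue;
    const mat Wj = W.rows(j * Cin, (j + 1) * Cin - 1);
    for (int s = 0; s < B; ++s) {
      const int base = s * T;
      Y.rows(base + lo, base + hi) +=
        X.rows(base + lo + o, base + hi + o) * Wj;
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& dY, const arma::mat& X,
                          const arma::mat& W, int k, int B, int T) {
  const int Cin = X.n_cols, Cout = dY.n_cols;
  const int left = (k - 1) / 2;
  mat dX(size(X), fill::zeros);
  mat dW(k * Cin, Cout, fill::zeros);
  rowvec db = sum(dY, 0);
  for (int j = 0; j < k; ++j) {
    const int o = j - left;
    const int lo = std::max(0, -o), hi = std::min(T - 1, T - 1 - o);
    if (lo > hi) continue;
    const mat Wjt = W.rows(j * Cin, (j + 1) * Cin - 1).t();
    for (int s = 0; s < B; ++s) {
      const int base = s * T;
      const mat dYb = dY.rows(base + lo, base + hi);
      dW.rows(j * Cin, (j + 1) * Cin - 1) +=
        X.rows(base + lo + o, base + hi + o).t() * dYb;
      dX.rows(base + lo + o, base + hi + o) += dYb * Wjt;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::mat add_bias_cpp(const arma::mat& M, const arma::vec& b) {
  arma::mat Y = M;
  Y.each_row() += b.t();
  return Y;
}
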