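#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// One-pole attack/release follower on instantaneous power. Attack applies
// while the input power exceeds the current estimate, release otherwise.
// [[Rcpp::export]]
arma::vec cpp_env_follow(const arma::vec& x2, double a_att, double a_rel) {
  vec env(x2.n_elem);
  double e = x2.n_elem > 0 ? x2[0] : 0.0;
  for (uword n = 0; n < x2.n_elem; ++n) {
    double a = (x2[n] > e) ? a_att : a_rel;
    e = a * e + (1.0 - a) * x2[n];
    env[n] = e;
  }
  return env;
}

static void im2col(const mat& Xp, uword K, uword stride, uword Lout, mat& col) {
  const uword Cin = Xp.n_rows;
  for (uword j = 0; j < Lout; ++j) {
    for (uword k = 0; k < K; ++k) {
      col.submat(k * Cin, j, (k + 1) * Cin - 1, j) = Xp.col(j * stride + k);
    }
  }
}

// 1-D convolution over a batch. X: (Cin, L, B); W: (Cout, Cin*K) with
// column layout c + k*Cin. Returns (Cout, Lout, B).
// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& X, const arma::mat& W, int K,
                          int stride, int pad_l, int pad_r) {
  const uword Cin = X.n_rows, L = X.n_cols, B = X.n_slices;
  const uword Lp = L + pad_l + pad_r;
  const uword Lout = (Lp - K) / stride + 1;
  const uword Cout = W.n_rows;
  cube Y(Cout, Lout, B);
  mat Xp(Cin, Lp, fill::zeros);
  mat col(Cin * K, Lout);
  for (uword b = 0; b < B; ++b) {
    Xp.zeros();
    Xp.cols(pad_l, pad_l + L - 1) = X.slice(b);
    im2col(Xp, K, stride, Lout, col);
    Y.slice(b) = W * col;
  }
  return Y;
}

// Gradients of the convolution: returns dX (Cin, L, B) and dW (Cout, Cin*K).
// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& X, const arma::mat& W,
                          const arma::cube& dY, int K, int stride,
                          int pad_l, int pad_r) {
  const uword Cin = X.n_rows, L = X.n_cols, B = X.n_slices;
  const uword Lp = L + pad_l + pad_r;
  const uword Lout = dY.n_cols;
  cube dX(Cin, L, B, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  mat Xp(Cin, Lp, fill::zeros);
  mat col(Cin * K, Lout);
  mat dXp(Cin, Lp);
  for (uword b = 0; b < B; ++b) {
    Xp.zeros();
    Xp.cols(pad_l, pad_l + L - 1) = X.slice(b);
    im2col(Xp, K, stride, Lout, col);
    dW += dY.slice(b) * col.t();
    mat dcol = W.t() * dY.slice(b);   // (Cin*K, Lout)
    dXp.zeros();
    for (uword j = 0; j < Lout; ++j) {
      for (uword k = 0; k < K; ++k) {
        dXp.col(j * stride + k) +=
          dcol.submat(k * Cin, j, (k + 1) * Cin - 1, j);
      }
    }
    dX.slice(b) = dXp.cols(pad_l, pad_l + L - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW);
}
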