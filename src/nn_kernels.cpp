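// Conv1D and LSTM forward/backward kernels for the CNN-LSTM engine.
// Tensor layout matches the R side: arrays [batch, time, channels] stored
// column-major, i.e. an arma::cube with rows = batch, cols = time,
// slices = channels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::vec;

static mat im2col(const cube& X, int k) {
  int B = X.n_rows, T = X.n_cols, C = X.n_slices;
  int To = T - k + 1;
  mat P(B * To, k * C);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c)
      P.col(j * C + c) = arma::vectorise(X.slice(c).cols(j, j + To - 1));
  return P;
}

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b) {
  int B = X.n_rows, T = X.n_cols;
  int k = W.n_rows / X.n_slices, F = W.n_cols;
  int To = T - k + 1;
  mat Y = im2col(X, k) * W;
  Y.each_row() += b.t();
  cube out(B, To, F);
  for (int f = 0; f < F; ++f)
    out.slice(f) = arma::reshape(Y.col(f), B, To);
  return out;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::cube& X, const arma::mat& W,
                    const arma::cube& dY) {
  int B = X.n_rows, T = X.n_cols, C = X.n_slices;
  int k = W.n_rows / C, F = W.n_cols;
  int To = T - k + 1;
  mat P = im2col(X, k);
  mat dYm(B * To, F);
  for (int f = 0; f < F; ++f)
    dYm.col(f) = arma::vectorise(dY.slice(f));
  mat dW = P.t() * dYm;
  vec db = arma::sum(dYm, 0).t();
  mat dP = dYm * W.t();
  cube dX(B, T, C, arma::fill::zeros);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c)
      dX.slice(c).cols(j, j + To - 1) += arma::reshape(dP.col(j * C + c), B, To);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// gate order along columns: input, forget, cell, output
// [[Rcpp::export]]
List lstm_fwd_cpp(const arma::cube& X, const arma::mat& Wx,
                  const arma::mat& Wh, const arma::vec& b) {
  int B = X.n_rows, T = X.n_cols, C = X.n_slices;
  int U = Wh.n_rows;
  cube I(B, U, T), Fg(B, U, T), G(B, U, T), O(B, U, T), Cs(B, U, T), Hs(B, U, T);
  mat h(B, U, arma::fill::zeros), c(B, U, arma::fill::zeros), Xt(B, C);
  for (int t = 0; t < T; ++t) {
    for (int cc = 0; cc < C; ++cc) Xt.col(cc) = X.slice(cc).col(t);
    mat Z = Xt * Wx + h * Wh;
    Z.each_row() += b.t();
    mat i_t = sigm(Z.cols(0, U - 1));
    mat f_t = sigm(Z.cols(U, 2 * U - 1));
    mat g_t = arma::tanh(Z.cols(2 * U, 3 * U - 1));
    mat o_t = sigm(Z.cols(3 * U, 4 * U - 1));
    c = f_t % c + i_t % g_t;
    h = o_t % arma::tanh(c);
    I.slice(t) = i_t; Fg.slice(t) = f_t; G.slice(t) = g_t; O.slice(t) = o_t;
    Cs.slice(t) = c; Hs.slice(t) = h;
  }
  return List::create(_["h"] = h, _["I"] = I, _["Fg"] = Fg, _["G"] = G,
                      _["O"] = O, _["Cs"] = Cs, _["Hs"] = Hs);
}

// [[Rcpp::export]]
List lstm_bwd_cpp(const arma::cube& X, const arma::mat& Wx,
                  const arma::mat& Wh, const arma::cube& I,
                  const arma::cube& Fg, const arma::cube& G,
                  const arma::cube& O, const arma::cube& Cs,
                  const arma::cube& Hs, const arma::mat& dh_last) {
  int B = X.n_rows, T = X.n_cols, C = X.n_slices;
  int U = Wh.n_rows;
  mat dWx(arma::size(Wx), arma::fill::zeros);
  mat dWh(arma::size(Wh), arma::fill::zeros);
  rowvec db(4 * U, arma::fill::zeros);
  cube dX(B, T, C, arma::fill::zeros);
  mat dh = dh_last, dc(B, U, arma::fill::zeros), Xt(B, C);
  for (int t = T - 1; t >= 0; --t) {
    const mat& i_t = I.slice(t); const mat& f_t = Fg.slice(t);
    const mat& g_t = G.slice(t); const mat& o_t = O.slice(t);
    mat tc = arma::tanh(Cs.slice(t));
    dc += dh % o_t % (1.0 - tc % tc);
    mat c_prev = (t > 0) ? Cs.slice(t - 1) : mat(B, U, arma::fill::zeros);
    mat h_prev = (t > 0) ? Hs.slice(t - 1) : mat(B, U, arma::fill::zeros);
    mat dZ(B, 4 * U);
    dZ.cols(0, U - 1) = (dc % g_t) % i_t % (1.0 - i_t);
    dZ.cols(U, 2 * U - 1) = (dc % c_prev) % f_t % (1.0 - f_t);
    dZ.cols(2 * U, 3 * U - 1) = (dc % i_t) % (1.0 - g_t % g_t);
    dZ.cols(3 * U, 4 * U - 1) = (dh % tc) % o_t % (1.0 - o_t);
    for (int cc = 0; cc < C; ++cc) Xt.col(cc) = X.slice(cc).col(t);
    dWx += Xt.t() * dZ;
    dWh += h_prev.t() * dZ;
    db += arma::sum(dZ, 0);
    mat dXt = dZ * Wx.t();
    for (int cc = 0; cc < C; ++cc) dX.slice(cc).col(t) = dXt.col(cc);
    dh = dZ * Wh.t();
    dc %= f_t;
  }
  return List::create(_["dX"] = dX, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db.t());
}
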