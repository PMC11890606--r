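// Time-loop kernels for the bidirectional LSTM context encoder.
//
// Batch layout: a batch of B sequences of length L is stored as a
// (B*L) x d matrix whose row (t-1)*B + b holds position t of sequence b.
// Padding positions carry zero input; the recurrence runs over every
// position (state evolves through bias and recurrent terms only).
//
// Gate column order: [input | forget | cell | output], each H wide.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
Rcpp::List lstm_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b,
                            int B, int L, bool reverse) {
  const int H = Wh.n_rows;
  if ((int)X.n_rows != B * L)
    Rcpp::stop("X must have B*L rows");
  if (!X.is_finite())
    Rcpp::stop("non-finite inputs to LSTM layer");
  mat XP = X * Wx;
  XP.each_row() += b.t();

  mat Hout(B * L, H, fill::zeros), Cout(B * L, H, fill::zeros);
  mat G(B * L, 4 * H, fill::zeros);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);

  for (int s = 0; s < L; ++s) {
    int t = reverse ? (L - 1 - s) : s;
    span rows(t * B, (t + 1) * B - 1);
    mat A = XP.rows(rows) + h * Wh;
    mat gi = sigm(A.cols(0, H - 1));
    mat gf = sigm(A.cols(H, 2 * H - 1));
    mat gg = tanh(A.cols(2 * H, 3 * H - 1));
    mat go = sigm(A.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    G(rows, span(0, H - 1)) = gi;
    G(rows, span(H, 2 * H - 1)) = gf;
    G(rows, span(2 * H, 3 * H - 1)) = gg;
    G(rows, span(3 * H, 4 * H - 1)) = go;
    Cout.rows(rows) = c;
    Hout.rows(rows) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hout,
                            Rcpp::Named("C") = Cout,
                            Rcpp::Named("G") = G);
}

// [[Rcpp::export(name = ".lstm_backward_cpp")]]
Rcpp::List lstm_backward_cpp(const arma::mat& dH, const arma::mat& X,
                             const arma::mat& Wx, const arma::mat& Wh,
                             const arma::mat& Hout, const arma::mat& Cout,
                             const arma::mat& G, int B, int L, bool reverse) {
  const int H = Wh.n_rows;
  const int D = X.n_cols;
  mat dX(B * L, D, fill::zeros);
  mat dWx(D, 4 * H, fill::zeros), dWh(H, 4 * H, fill::zeros);
  vec db(4 * H, fill::zeros);
  mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);

  // walk timesteps in the opposite order of the forward pass
  for (int s = L - 1; s >= 0; --s) {
    int t = reverse ? (L - 1 - s) : s;
    span rows(t * B, (t + 1) * B - 1);
    bool first = (s == 0);  // first step processed in the forward pass
    int tp = reverse ? (t + 1) : (t - 1);

    dh += dH.rows(rows);
    mat gi = G(rows, span(0, H - 1));
    mat gf = G(rows, span(H, 2 * H - 1));
    mat gg = G(rows, span(2 * H, 3 * H - 1));
    mat go = G(rows, span(3 * H, 4 * H - 1));
    mat c_t = Cout.rows(rows);
    mat tc = tanh(c_t);
    mat c_prev = first ? mat(B, H, fill::zeros)
                       : Cout.rows(span(tp * B, (tp + 1) * B - 1));
    mat h_prev = first ? mat(B, H, fill::zeros)
                       : Hout.rows(span(tp * B, (tp + 1) * B - 1));

    mat dgo = dh % tc;
    dc += dh % go % (1.0 - tc % tc);
    mat dgi = dc % gg;
    mat dgf = dc % c_prev;
    mat dgg = dc % gi;

    mat dA(B, 4 * H);
    dA.cols(0, H - 1) = dgi % gi % (1.0 - gi);
    dA.cols(H, 2 * H - 1) = dgf % gf % (1.0 - gf);
    dA.cols(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
    dA.cols(3 * H, 4 * H - 1) = dgo % go % (1.0 - go);

    dX.rows(rows) = dA * Wx.t();
    dWx += X.rows(rows).t() * dA;
    dWh += h_prev.t() * dA;
    db += sum(dA, 0).t();

    dh = dA * Wh.t();
    dc = dc % gf;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db);
}
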