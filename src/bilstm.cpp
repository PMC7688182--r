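// Bi-directional LSTM sequence classifier core: forward pass and
// backpropagation through time for a per-timestep two-class softmax output.
// Parameters follow the standard LSTM cell with gate order (input, forget,
// cell, output) stacked row-wise in the 4H x D input weights, 4H x H
// recurrent weights and 4H bias per direction, plus a 2 x 2H output layer.
// The optimizer lives in R; this file only computes probabilities, loss and
// exact gradients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec sigmoid(const vec& x) {
  return 1.0 / (1.0 + exp(-x));
}

struct DirCache {
  mat I, F, G, O;   // gate activations, H x T
  mat C, TC, H;     // cell state, tanh(cell), hidden state, H x T
};

// Run one direction. `idx` gives the processing order (forward: 0..T-1,
// backward: T-1..0).
static void run_direction(const mat& WxX, const mat& Wh, const vec& b,
                          const uvec& idx, DirCache& cc) {
  const uword H = Wh.n_rows / 4;
  const uword T = WxX.n_cols;
  cc.I.set_size(H, T); cc.F.set_size(H, T); cc.G.set_size(H, T);
  cc.O.set_size(H, T); cc.C.set_size(H, T); cc.TC.set_size(H, T);
  cc.H.set_size(H, T);
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    const uword t = idx(s);
    vec a = WxX.col(t) + Wh * h + b;
    vec i = sigmoid(a.rows(0, H - 1));
    vec f = sigmoid(a.rows(H, 2 * H - 1));
    vec g = tanh(a.rows(2 * H, 3 * H - 1));
    vec o = sigmoid(a.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    vec tc = tanh(c);
    h = o % tc;
    cc.I.col(t) = i; cc.F.col(t) = f; cc.G.col(t) = g; cc.O.col(t) = o;
    cc.C.col(t) = c; cc.TC.col(t) = tc; cc.H.col(t) = h;
  }
}

static uvec order_fwd(uword T) {
  return regspace<uvec>(0, T - 1);
}
static uvec order_bwd(uword T) {
  return regspace<uvec>(T - 1, 0);
}

static mat output_probs(const mat& Wo, const vec& bo,
                        const DirCache& cf, const DirCache& cb) {
  mat Z = Wo * join_cols(cf.H, cb.H);
  Z.each_col() += bo;
  rowvec m = max(Z, 0);
  Z.each_row() -= m;
  mat E = exp(Z);
  rowvec s = sum(E, 0);
  E.each_row() /= s;
  return E;  // 2 x T
}

// [[Rcpp::export]]
arma::mat cpp_bilstm_forward(const arma::mat& Wx_f, const arma::mat& Wh_f,
                             const arma::vec& b_f, const arma::mat& Wx_b,
                             const arma::mat& Wh_b, const arma::vec& b_b,
                             const arma::mat& Wo, const arma::vec& bo,
                             const arma::mat& X) {
  const uword T = X.n_cols;
  DirCache cf, cb;
  run_direction(Wx_f * X, Wh_f, b_f, order_fwd(T), cf);
  run_direction(Wx_b * X, Wh_b, b_b, order_bwd(T), cb);
  return output_probs(Wo, bo, cf, cb);
}

// Backward pass for one direction given dH (H x T) flowing into its hidden
// states. Accumulates gradients for Wx, Wh, b.
static void backprop_direction(const mat& X, const mat& Wh,
                               const uvec& idx, const DirCache& cc,
                               const mat& dH, mat& dWx, mat& dWh, vec& db) {
  const uword H = Wh.n_rows / 4;
  const uword T = X.n_cols;
  dWx.zeros(4 * H, X.n_rows);
  dWh.zeros(4 * H, H);
  db.zeros(4 * H);
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (uword s = T; s-- > 0;) {
    const uword t = idx(s);
    vec hprev(H, fill::zeros), cprev(H, fill::zeros);
    if (s > 0) {
      hprev = cc.H.col(idx(s - 1));
      cprev = cc.C.col(idx(s - 1));
    }
    vec i = cc.I.col(t), f = cc.F.col(t), g = cc.G.col(t), o = cc.O.col(t);
    vec tc = cc.TC.col(t);
    vec dh = dH.col(t) + dh_next;
    vec do_ = dh % tc;
    vec dc = dc_next + dh % o % (1.0 - tc % tc);
    vec di = dc % g;
    vec df = dc % cprev;
    vec dg = dc % i;
    vec da(4 * H);
    da.rows(0, H - 1) = di % i % (1.0 - i);
    da.rows(H, 2 * H - 1) = df % f % (1.0 - f);
    da.rows(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    da.rows(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dWx += da * X.col(t).t();
    dWh += da * hprev.t();
    db += da;
    dh_next = Wh.t() * da;
    dc_next = dc % f;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_grad(const arma::mat& Wx_f, const arma::mat& Wh_f,
                           const arma::vec& b_f, const arma::mat& Wx_b,
                           const arma::mat& Wh_b, const arma::vec& b_b,
                           const arma::mat& Wo, const arma::vec& bo,
                           const arma::mat& X, const arma::ivec& y) {
  const uword T = X.n_cols;
  const uword H = Wh_f.n_rows / 4;
  if (y.n_elem != T) Rcpp::stop("label length must match sequence length");

  DirCache cf, cb;
  uvec idf = order_fwd(T), idb = order_bwd(T);
  run_direction(Wx_f * X, Wh_f, b_f, idf, cf);
  run_direction(Wx_b * X, Wh_b, b_b, idb, cb);
  mat P = output_probs(Wo, bo, cf, cb);

  // mean cross-entropy over timesteps
  double loss = 0.0;
  mat dZ = P;
  for (uword t = 0; t < T; ++t) {
    const uword k = (y(t) != 0) ? 1 : 0;
    loss -= std::log(std::max(P(k, t), 1e-12));
    dZ(k, t) -= 1.0;
  }
  loss /= T;
  dZ /= (double)T;

  mat Hcat = join_cols(cf.H, cb.H);
  mat dWo = dZ * Hcat.t();
  vec dbo = sum(dZ, 1);
  mat dHcat = Wo.t() * dZ;  // 2H x T
  mat dHf = dHcat.rows(0, H - 1);
  mat dHb = dHcat.rows(H, 2 * H - 1);

  mat dWx_f, dWh_f, dWx_b, dWh_b;
  vec db_f, db_b;
  backprop_direction(X, Wh_f, idf, cf, dHf, dWx_f, dWh_f, db_f);
  backprop_direction(X, Wh_b, idb, cb, dHb, dWx_b, dWh_b, db_b);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("Wx_f") = dWx_f, Rcpp::Named("Wh_f") = dWh_f,
    Rcpp::Named("b_f") = db_f,
    Rcpp::Named("Wx_b") = dWx_b, Rcpp::Named("Wh_b") = dWh_b,
    Rcpp::Named("b_b") = db_b,
    Rcpp::Named("Wo") = dWo, Rcpp::Named("bo") = dbo);
}
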