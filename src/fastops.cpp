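// Compiled kernels for the two sequential hot spots of the network:
// the LSTM time-step recursion and the per-sample multi-head attention.
// Layout contracts match the R callers:
//  - LSTM matrices are position-major: row r is sample ((r-1) % n) + 1 at
//    position floor((r-1)/n) + 1.
//  - Attention matrices are sample-major: the T rows of sample i are the
//    contiguous block [(i-1)*T, i*T).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// XW: (n*T, 4H) input projections incl. bias; Wh: (H, 4H)
// Returns hidden states, post-activation gates and cell states per step.
// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& XW, const arma::mat& Wh,
                            int n, int T, bool reverse) {
  const int H = Wh.n_rows;
  mat Hout(n * T, H, fill::zeros);
  cube G(n, 4 * H, T);  // gates i,f,g,o after nonlinearity
  cube C(n, H, T);      // cell states
  mat h(n, H, fill::zeros), c(n, H, fill::zeros);
  for (int s = 0; s < T; ++s) {
    const int t = reverse ? (T - 1 - s) : s;
    mat z = XW.rows(t * n, (t + 1) * n - 1) + h * Wh;
    mat ii = sigm(z.cols(0, H - 1));
    mat ff = sigm(z.cols(H, 2 * H - 1));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat oo = sigm(z.cols(3 * H, 4 * H - 1));
    c = ff % c + ii % gg;
    mat tc = tanh(c);
    h = oo % tc;
    Hout.rows(t * n, (t + 1) * n - 1) = h;
    G.slice(t).cols(0, H - 1) = ii;
    G.slice(t).cols(H, 2 * H - 1) = ff;
    G.slice(t).cols(2 * H, 3 * H - 1) = gg;
    G.slice(t).cols(3 * H, 4 * H - 1) = oo;
    C.slice(t) = c;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hout,
                            Rcpp::Named("G") = G,
                            Rcpp::Named("C") = C);
}

// Backward through time; returns pre-activation gate gradients dZ (n*T, 4H)
// and dWh. The caller finishes dWx / db / dX with single large products.
// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& dH, const arma::mat& Wh,
                             const arma::cube& G, const arma::cube& C,
                             const arma::mat& Hout, int n, int T,
                             bool reverse) {
  const int H = Wh.n_rows;
  mat dZ(n * T, 4 * H, fill::zeros);
  mat dWh(H, 4 * H, fill::zeros);
  mat dh_next(n, H, fill::zeros), dc_next(n, H, fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    const int t = reverse ? (T - 1 - s) : s;
    const int tprev = reverse ? (t + 1) : (t - 1);
    mat ii = G.slice(t).cols(0, H - 1);
    mat ff = G.slice(t).cols(H, 2 * H - 1);
    mat gg = G.slice(t).cols(2 * H, 3 * H - 1);
    mat oo = G.slice(t).cols(3 * H, 4 * H - 1);
    mat c_prev = (s == 0) ? mat(n, H, fill::zeros) : mat(C.slice(tprev));
    mat h_prev = (s == 0) ? mat(n, H, fill::zeros)
                          : mat(Hout.rows(tprev * n, (tprev + 1) * n - 1));
    mat tc = tanh(C.slice(t));
    mat dh = dH.rows(t * n, (t + 1) * n - 1) + dh_next;
    mat do_ = dh % tc;
    mat dc = dc_next + dh % oo % (1.0 - tc % tc);
    mat dz(n, 4 * H);
    dz.cols(0, H - 1) = (dc % gg) % ii % (1.0 - ii);
    dz.cols(H, 2 * H - 1) = (dc % c_prev) % ff % (1.0 - ff);
    dz.cols(2 * H, 3 * H - 1) = (dc % ii) % (1.0 - gg % gg);
    dz.cols(3 * H, 4 * H - 1) = do_ % oo % (1.0 - oo);
    dZ.rows(t * n, (t + 1) * n - 1) = dz;
    dWh += h_prev.t() * dz;
    dh_next = dz * Wh.t();
    dc_next = dc % ff;
  }
  return Rcpp::List::create(Rcpp::Named("dZ") = dZ,
                            Rcpp::Named("dWh") = dWh);
}

// Scaled dot-product attention for every (sample, head) pair.
// Q,K,V: (n*T, D) sample-major. Returns the concatenated head contexts and
// the row-stochastic attention matrices as a cube (T, T, n*heads), head
// fastest within sample.
// [[Rcpp::export]]
Rcpp::List attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                            const arma::mat& V, int n, int T, int heads) {
  const int D = Q.n_cols;
  const int dk = D / heads;
  const double scal = 1.0 / std::sqrt((double) dk);
  mat Ctx(n * T, D, fill::zeros);
  cube A(T, T, n * heads);
  for (int i = 0; i < n; ++i) {
    const int r0 = i * T, r1 = (i + 1) * T - 1;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dk, c1 = (h + 1) * dk - 1;
      mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scal;
      S.each_col() -= max(S, 1);
      mat E = exp(S);
      E.each_col() /= sum(E, 1);
      A.slice(i * heads + h) = E;
      Ctx.submat(r0, c0, r1, c1) = E * V.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("Ctx") = Ctx, Rcpp::Named("A") = A);
}

// [[Rcpp::export]]
Rcpp::List attn_backward_cpp(const arma::mat& Q, const arma::mat& K,
                             const arma::mat& V, const arma::cube& A,
                             const arma::mat& dCtx, int n, int T, int heads) {
  const int D = Q.n_cols;
  const int dk = D / heads;
  const double scal = 1.0 / std::sqrt((double) dk);
  mat dQ(n * T, D, fill::zeros), dK(n * T, D, fill::zeros),
      dV(n * T, D, fill::zeros);
  for (int i = 0; i < n; ++i) {
    const int r0 = i * T, r1 = (i + 1) * T - 1;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dk, c1 = (h + 1) * dk - 1;
      const mat& Ah = A.slice(i * heads + h);
      mat dCh = dCtx.submat(r0, c0, r1, c1);
      mat dA = dCh * V.submat(r0, c0, r1, c1).t();
      dV.submat(r0, c0, r1, c1) = Ah.t() * dCh;
      mat dS = Ah % (dA.each_col() - sum(dA % Ah, 1)) * scal;
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1);
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
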