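// Batched LSTM recurrence kernels. The input projection X * Wx' for all
// timesteps is one BLAS call on the R side; these kernels run the sequential
// part (gates, cell state, hidden state, and their adjoints).
//
// Layout: sequence batches are (B*T) x K matrices whose row block
// (t*B) .. (t*B + B - 1) holds timestep t (0-based), matching the
// column-major flattening of a [B, T, K] R array. Gate order is i, f, g, o.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline double sigm1(double v) { return 1.0 / (1.0 + std::exp(-v)); }

// Forward recurrence. M holds the precomputed input projections (BT x 4H).
// Returns the hidden sequence H (BT x H) and, when keep_cache, the activated
// gate block G (BT x 4H), the pre-update cell state Cprev and tanh(c).
// [[Rcpp::export]]
List lstm_seq_forward(const arma::mat& M, const arma::mat& Wh,
                      const arma::vec& b, int B, int T, bool reverse,
                      bool keep_cache) {
  const int H = Wh.n_cols;
  const mat Wh_t = Wh.t();
  const rowvec bt = b.t();
  const uword n = M.n_rows;
  mat Hout(n, H);
  mat G, Cprev, Tc;
  if (keep_cache) { G.set_size(n, 4 * H); Cprev.set_size(n, H); Tc.set_size(n, H); }
  mat h(B, H, fill::zeros), c(B, H, fill::zeros), A(B, 4 * H), tc(B, H);
  for (int k = 0; k < T; ++k) {
    const int t = reverse ? (T - 1 - k) : k;
    const span rows(t * B, t * B + B - 1);
    A = M.rows(rows);
    A += h * Wh_t;
    A.each_row() += bt;
    A.cols(0, 2 * H - 1).transform([](double v) { return sigm1(v); });
    A.cols(2 * H, 3 * H - 1).transform([](double v) { return std::tanh(v); });
    A.cols(3 * H, 4 * H - 1).transform([](double v) { return sigm1(v); });
    if (keep_cache) Cprev.rows(rows) = c;
    c = A.cols(H, 2 * H - 1) % c + A.cols(0, H - 1) % A.cols(2 * H, 3 * H - 1);
    tc = tanh(c);
    h = A.cols(3 * H, 4 * H - 1) % tc;
    Hout.rows(rows) = h;
    if (keep_cache) { G.rows(rows) = A; Tc.rows(rows) = tc; }
  }
  if (keep_cache) {
    return List::create(_["H"] = Hout, _["G"] = G, _["c_prev"] = Cprev,
                        _["tc"] = Tc);
  }
  return List::create(_["H"] = Hout);
}

// Backward recurrence: dH is the upstream gradient on the hidden sequence.
// Returns dM (gradient on the input projections), dWh and db.
// [[Rcpp::export]]
List lstm_seq_backward(const arma::mat& dH, const arma::mat& Hout,
                       const arma::mat& G, const arma::mat& Cprev,
                       const arma::mat& Tc, const arma::mat& Wh,
                       int B, int T, bool reverse) {
  const int H = Wh.n_cols;
  mat dM(dH.n_rows, 4 * H);
  mat dWh(4 * H, H, fill::zeros);
  vec db(4 * H, fill::zeros);
  mat dh_carry(B, H, fill::zeros), dc(B, H, fill::zeros);
  mat dA(B, 4 * H), dh(B, H);
  for (int k = T - 1; k >= 0; --k) {
    const int t = reverse ? (T - 1 - k) : k;
    const span rows(t * B, t * B + B - 1);
    dh = dH.rows(rows);
    dh += dh_carry;
    const auto gi = G(rows, span(0, H - 1));
    const auto gf = G(rows, span(H, 2 * H - 1));
    const auto gg = G(rows, span(2 * H, 3 * H - 1));
    const auto go = G(rows, span(3 * H, 4 * H - 1));
    const auto tc = Tc.rows(rows);
    dc += dh % go % (1.0 - tc % tc);
    dA.cols(0, H - 1)         = dc % gg % gi % (1.0 - gi);
    dA.cols(H, 2 * H - 1)     = dc % Cprev.rows(rows) % gf % (1.0 - gf);
    dA.cols(2 * H, 3 * H - 1) = dc % gi % (1.0 - gg % gg);
    dA.cols(3 * H, 4 * H - 1) = dh % tc % go % (1.0 - go);
    dc %= gf;
    dM.rows(rows) = dA;
    if (k > 0) {
      const int tp = reverse ? (T - k) : (k - 1);
      dWh += dA.t() * Hout.rows(span(tp * B, tp * B + B - 1));
    }
    db += sum(dA, 0).t();
    dh_carry = dA * Wh;
  }
  return List::create(_["dM"] = dM, _["dWh"] = dWh, _["db"] = db);
}
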