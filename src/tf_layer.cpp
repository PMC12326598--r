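// Transformer block forward/backward, the training hot path.
//
// Mirrors the reference R implementation exactly (pre-norm block:
// LN -> multi-head self-attention -> residual, LN -> GELU feed-forward
// -> residual); the R versions remain in the package and the test suite
// asserts numerical agreement between the two routes. The forward cache
// lives in an external pointer so no activation tensors are copied
// across the R/C++ boundary.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::XPtr;

static const double LN_EPS = 1e-5;
static const double GELU_C = 1.702;  // sigmoid-GELU gate slope

struct LayerCache {
  mat l1_xhat, l1_y, l2_xhat, l2_y;
  vec l1_inv, l2_inv;
  mat Q, K, V, O;
  cube P;
  mat F1, sg, A;
  int B, T, nh;
};

// row-wise layer norm; fills xhat and inv for the backward pass
static mat ln_fwd_c(const mat& x, const rowvec& g, const rowvec& b,
                    mat& xhat, vec& inv) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = mean(square(xc), 1);
  inv = 1.0 / sqrt(v + LN_EPS);
  xhat = xc.each_col() % inv;
  mat y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat ln_bwd_c(const mat& dy, const mat& xhat, const vec& inv,
                    const rowvec& g, rowvec& dg, rowvec& db) {
  dg = sum(dy % xhat, 0);
  db = sum(dy, 0);
  mat dxh = dy.each_row() % g;
  vec m1 = mean(dxh, 1);
  vec m2 = mean(dxh % xhat, 1);
  mat dx = dxh.each_col() - m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  return dx;
}

static mat softmax_rows_c(mat z) {
  z.each_col() -= max(z, 1);
  z = exp(z);
  z.each_col() /= sum(z, 1);
  return z;
}

// [[Rcpp::export(name = ".tf_layer_fwd_cpp")]]
List tf_layer_fwd_cpp(const arma::mat& X, const List& p, int B, int T,
                      int nh, const arma::imat& keymask) {
  int H = X.n_cols;
  int dh = H / nh;
  double scale = 1.0 / std::sqrt((double) dh);

  rowvec ln1_g = p["ln1_g"], ln1_b = p["ln1_b"];
  mat Wq = p["Wq"], Wk = p["Wk"], Wv = p["Wv"], Wo = p["Wo"];
  rowvec bq = p["bq"], bk = p["bk"], bv = p["bv"], bo = p["bo"];
  rowvec ln2_g = p["ln2_g"], ln2_b = p["ln2_b"];
  mat W1 = p["W1"], W2 = p["W2"];
  rowvec b1 = p["b1"], b2 = p["b2"];

  XPtr<LayerCache> cp(new LayerCache(), true);
  LayerCache& c = *cp;
  c.B = B; c.T = T; c.nh = nh;

  c.l1_y = ln_fwd_c(X, ln1_g, ln1_b, c.l1_xhat, c.l1_inv);
  c.Q = c.l1_y * Wq; c.Q.each_row() += bq;
  c.K = c.l1_y * Wk; c.K.each_row() += bk;
  c.V = c.l1_y * Wv; c.V.each_row() += bv;

  c.O.zeros(X.n_rows, H);
  c.P.set_size(T, T, (uword)(B * nh));
  for (int b = 0; b < B; ++b) {
    uvec pad;
    {
      std::vector<uword> padv;
      for (int t = 0; t < T; ++t) if (keymask(b, t) == 0) padv.push_back(t);
      pad = uvec(padv);
    }
    int r0 = b * T;
    for (int a = 0; a < nh; ++a) {
      int c0 = a * dh;
      mat S = c.Q.submat(r0, c0, r0 + T - 1, c0 + dh - 1) *
        c.K.submat(r0, c0, r0 + T - 1, c0 + dh - 1).t() * scale;
      for (uword j = 0; j < pad.n_elem; ++j) S.col(pad(j)).fill(-1e9);
      mat Pm = softmax_rows_c(S);
      c.P.slice(b * nh + a) = Pm;
      c.O.submat(r0, c0, r0 + T - 1, c0 + dh - 1) =
        Pm * c.V.submat(r0, c0, r0 + T - 1, c0 + dh - 1);
    }
  }
  mat att = c.O * Wo; att.each_row() += bo;
  mat X1 = X + att;
  c.l2_y = ln_fwd_c(X1, ln2_g, ln2_b, c.l2_xhat, c.l2_inv);
  c.F1 = c.l2_y * W1; c.F1.each_row() += b1;
  c.sg = 1.0 / (1.0 + exp(-GELU_C * c.F1));
  c.A = c.F1 % c.sg;
  mat X2 = c.A * W2; X2.each_row() += b2;
  X2 += X1;

  return List::create(Named("y") = X2, Named("cache") = cp);
}

// [[Rcpp::export(name = ".tf_layer_bwd_cpp")]]
List tf_layer_bwd_cpp(const arma::mat& dY, const List& p, SEXP cache) {
  XPtr<LayerCache> cp(cache);
  LayerCache& c = *cp;
  int B = c.B, T = c.T, nh = c.nh;
  int H = dY.n_cols;
  int dh = H / nh;
  double scale = 1.0 / std::sqrt((double) dh);

  mat Wq = p["Wq"], Wk = p["Wk"], Wv = p["Wv"], Wo = p["Wo"];
  mat W1 = p["W1"], W2 = p["W2"];
  rowvec ln1_g = p["ln1_g"], ln2_g = p["ln2_g"];

  // feed-forward
  mat dW2 = c.A.t() * dY;
  rowvec db2 = sum(dY, 0);
  mat dA = dY * W2.t();
  mat dF1 = dA % (c.sg % (1.0 + GELU_C * c.F1 % (1.0 - c.sg)));
  mat dW1 = c.l2_y.t() * dF1;
  rowvec db1 = sum(dF1, 0);
  mat dl2 = dF1 * W1.t();
  rowvec dln2_g, dln2_b;
  mat dX1 = dY + ln_bwd_c(dl2, c.l2_xhat, c.l2_inv, ln2_g, dln2_g, dln2_b);

  // attention output projection
  mat dWo = c.O.t() * dX1;
  rowvec dbo = sum(dX1, 0);
  mat dO = dX1 * Wo.t();

  mat dQ(size(dO), fill::zeros), dK(size(dO), fill::zeros),
      dV(size(dO), fill::zeros);
  for (int b = 0; b < B; ++b) {
    int r0 = b * T;
    for (int a = 0; a < nh; ++a) {
      int c0 = a * dh;
      const mat& Pm = c.P.slice(b * nh + a);
      mat dOh = dO.submat(r0, c0, r0 + T - 1, c0 + dh - 1);
      mat dP = dOh * c.V.submat(r0, c0, r0 + T - 1, c0 + dh - 1).t();
      dV.submat(r0, c0, r0 + T - 1, c0 + dh - 1) = Pm.t() * dOh;
      mat dS = Pm % (dP.each_col() - sum(dP % Pm, 1));
      dQ.submat(r0, c0, r0 + T - 1, c0 + dh - 1) =
        dS * c.K.submat(r0, c0, r0 + T - 1, c0 + dh - 1) * scale;
      dK.submat(r0, c0, r0 + T - 1, c0 + dh - 1) =
        dS.t() * c.Q.submat(r0, c0, r0 + T - 1, c0 + dh - 1) * scale;
    }
  }
  mat dWq = c.l1_y.t() * dQ; rowvec dbq = sum(dQ, 0);
  mat dWk = c.l1_y.t() * dK; rowvec dbk = sum(dK, 0);
  mat dWv = c.l1_y.t() * dV; rowvec dbv = sum(dV, 0);
  mat dl1 = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  rowvec dln1_g, dln1_b;
  mat dX = dX1 + ln_bwd_c(dl1, c.l1_xhat, c.l1_inv, ln1_g, dln1_g, dln1_b);

  List g = List::create(
    Named("ln1_g") = dln1_g, Named("ln1_b") = dln1_b,
    Named("Wq") = dWq, Named("bq") = dbq,
    Named("Wk") = dWk, Named("bk") = dbk,
    Named("Wv") = dWv, Named("bv") = dbv,
    Named("Wo") = dWo, Named("bo") = dbo,
    Named("ln2_g") = dln2_g, Named("ln2_b") = dln2_b,
    Named("W1") = dW1, Named("b1") = db1,
    Named("W2") = dW2, Named("b2") = db2);
  return List::create(Named("dx") = dX, Named("grads") = g);
}
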