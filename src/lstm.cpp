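// Single-layer LSTM regression: full-sequence forward pass, backpropagation
// through time, and Adam training on the RMSE loss. Gate ordering throughout
// is f (forget), i (input), g (cell candidate), o (output); the stacked
// weight matrix W is 4H x (H + D) acting on [h_{t-1}; x_t], b is 4H, and a
// fully connected layer v (H) + c maps h_t to the scalar regression output.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec sigmoid(const vec& z) { return 1.0 / (1.0 + exp(-z)); }

struct Caches {
  mat f, i, g, o, C, tc, h;   // H x T
  vec yhat;                   // T
};

static Caches forward_pass(const mat& X, const mat& W, const vec& b,
                           const vec& v, double c0,
                           const vec& h0, const vec& C0) {
  const uword T = X.n_rows;
  const uword H = v.n_elem;
  Caches cc;
  cc.f.set_size(H, T); cc.i.set_size(H, T); cc.g.set_size(H, T);
  cc.o.set_size(H, T); cc.C.set_size(H, T); cc.tc.set_size(H, T);
  cc.h.set_size(H, T); cc.yhat.set_size(T);
  vec h = h0, C = C0;
  for (uword t = 0; t < T; ++t) {
    vec hx = join_cols(h, X.row(t).t());
    vec z = W * hx + b;
    vec f = sigmoid(z.subvec(0, H - 1));
    vec i = sigmoid(z.subvec(H, 2 * H - 1));
    vec g = tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = sigmoid(z.subvec(3 * H, 4 * H - 1));
    C = f % C + i % g;
    vec tc = tanh(C);
    h = o % tc;
    cc.f.col(t) = f; cc.i.col(t) = i; cc.g.col(t) = g; cc.o.col(t) = o;
    cc.C.col(t) = C; cc.tc.col(t) = tc; cc.h.col(t) = h;
    cc.yhat(t) = dot(v, h) + c0;
  }
  return cc;
}

// RMSE loss and gradients over the full sequence.
static double backward_pass(const mat& X, const vec& y, const mat& W,
                            const vec& v, const vec& h0, const vec& C0,
                            const Caches& cc,
                            mat& dW, vec& db, vec& dv, double& dc) {
  const uword T = X.n_rows;
  const uword H = v.n_elem;
  vec e = cc.yhat - y;
  double rmse = std::sqrt(mean(square(e)));
  vec dy = e / (double(T) * std::max(rmse, 1e-12));   // dRMSE/dyhat

  dW.zeros(); db.zeros(); dv.zeros(); dc = 0.0;
  vec dh_next(H, fill::zeros), dC_next(H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    vec h = cc.h.col(t);
    dv += dy(t) * h;
    dc += dy(t);
    vec dh = dy(t) * v + dh_next;
    vec o = cc.o.col(t), tc = cc.tc.col(t), f = cc.f.col(t),
        i = cc.i.col(t), g = cc.g.col(t);
    vec dC = dh % o % (1.0 - square(tc)) + dC_next;
    vec Cprev = (t == 0) ? C0 : cc.C.col(t - 1);
    vec hprev = (t == 0) ? h0 : cc.h.col(t - 1);
    vec df = dC % Cprev % f % (1.0 - f);
    vec di = dC % g % i % (1.0 - i);
    vec dg = dC % i % (1.0 - square(g));
    vec do_ = dh % tc % o % (1.0 - o);
    vec dz = join_cols(join_cols(df, di), join_cols(dg, do_));
    vec hx = join_cols(hprev, X.row(t).t());
    dW += dz * hx.t();
    db += dz;
    vec dhx = W.t() * dz;
    dh_next = dhx.subvec(0, H - 1);
    dC_next = dC % f;
  }
  return rmse;
}

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& X, const arma::mat& W,
                            const arma::vec& b, const arma::vec& v, double c0,
                            const arma::vec& h0, const arma::vec& C0) {
  Caches cc = forward_pass(X, W, b, v, c0, h0, C0);
  const uword T = X.n_rows;
  return Rcpp::List::create(
      Rcpp::Named("yhat") = cc.yhat,
      Rcpp::Named("h_last") = vec(cc.h.col(T - 1)),
      Rcpp::Named("C_last") = vec(cc.C.col(T - 1)));
}

// [[Rcpp::export]]
Rcpp::List lstm_loss_grad_cpp(const arma::mat& X, const arma::vec& y,
                              const arma::mat& W, const arma::vec& b,
                              const arma::vec& v, double c0,
                              const arma::vec& h0, const arma::vec& C0) {
  Caches cc = forward_pass(X, W, b, v, c0, h0, C0);
  mat dW(size(W)); vec db(b.n_elem); vec dv(v.n_elem); double dc;
  double rmse = backward_pass(X, y, W, v, h0, C0, cc, dW, db, dv, dc);
  return Rcpp::List::create(
      Rcpp::Named("loss") = rmse,
      Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
      Rcpp::Named("dv") = dv, Rcpp::Named("dc") = dc);
}

// [[Rcpp::export]]
Rcpp::List lstm_fit_cpp(const arma::mat& X, const arma::vec& y,
                        arma::mat W, arma::vec b, arma::vec v, double c0,
                        int epochs, double lr, double clip) {
  const uword H = v.n_elem;
  const uword T = X.n_rows;
  vec h0(H, fill::zeros), C0(H, fill::zeros);
  mat dW(size(W)), mW(size(W), fill::zeros), vW(size(W), fill::zeros);
  vec db(b.n_elem), mb(b.n_elem, fill::zeros), vb(b.n_elem, fill::zeros);
  vec dv(H), mv(H, fill::zeros), vv(H, fill::zeros);
  double dc = 0, mc = 0, vc = 0;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  vec trace(epochs, fill::zeros);
  bool diverged = false;

  for (int ep = 0; ep < epochs; ++ep) {
    Caches cc = forward_pass(X, W, b, v, c0, h0, C0);
    double rmse = backward_pass(X, y, W, v, h0, C0, cc, dW, db, dv, dc);
    trace(ep) = rmse;
    if (!std::isfinite(rmse)) { diverged = true; break; }

    // global-norm gradient clipping
    double gn = std::sqrt(accu(square(dW)) + accu(square(db)) +
                          accu(square(dv)) + dc * dc);
    if (clip > 0 && gn > clip) {
      double s = clip / gn;
      dW *= s; db *= s; dv *= s; dc *= s;
    }
    double t_adam = ep + 1;
    double bc1 = 1.0 - std::pow(beta1, t_adam);
    double bc2 = 1.0 - std::pow(beta2, t_adam);
    mW = beta1 * mW + (1 - beta1) * dW;  vW = beta2 * vW + (1 - beta2) * square(dW);
    mb = beta1 * mb + (1 - beta1) * db;  vb = beta2 * vb + (1 - beta2) * square(db);
    mv = beta1 * mv + (1 - beta1) * dv;  vv = beta2 * vv + (1 - beta2) * square(dv);
    mc = beta1 * mc + (1 - beta1) * dc;  vc = beta2 * vc + (1 - beta2) * dc * dc;
    W -= lr * (mW / bc1) / (sqrt(vW / bc2) + eps);
    b -= lr * (mb / bc1) / (sqrt(vb / bc2) + eps);
    v -= lr * (mv / bc1) / (sqrt(vv / bc2) + eps);
    c0 -= lr * (mc / bc1) / (std::sqrt(vc / bc2) + eps);
  }

  Caches cc = forward_pass(X, W, b, v, c0, h0, C0);
  vec e = cc.yhat - y;
  double final_rmse = std::sqrt(mean(square(e)));
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("b") = b,
      Rcpp::Named("v") = v, Rcpp::Named("c") = c0,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("final_rmse") = final_rmse,
      Rcpp::Named("fitted") = cc.yhat,
      Rcpp::Named("h_last") = vec(cc.h.col(T - 1)),
      Rcpp::Named("C_last") = vec(cc.C.col(T - 1)),
      Rcpp::Named("diverged") = diverged);
}
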