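// Core forward/backward passes for the bilateral simple recurrent network.
// The R-level API (forward_trial, train_step, train, retrain) wraps these;
// weight containers live in an R list so that lesioning and measurement
// code can manipulate them directly. All trial-local buffers live in a
// Workspace so the training loop runs without per-presentation allocation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

const int N_TICKS = 6;
const int N_SLOTS = 3;

struct Net {
  mat Win_l, Win_r, Wctx_l, Wctx_r, W12_l, W12_r, Wout_l, Wout_r;
  mat Wx1_lr, Wx1_rl, Wx2_lr, Wx2_rl;
  mat Mx1_lr, Mx1_rl, Mx2_lr, Mx2_rl;
  rowvec b_l1, b_r1, b_l2, b_r2, b_out;
  rowvec alive_l1, alive_r1, alive_l2, alive_r2;
  double g_l1, g_r1, g_l2, g_r2;
  bool neg_only;
  int nio, nL, nR;
};

Net load_net(const List& s) {
  Net n;
  n.Win_l = as<mat>(s["W_in_l"]);   n.Win_r = as<mat>(s["W_in_r"]);
  n.Wctx_l = as<mat>(s["W_ctx_l"]); n.Wctx_r = as<mat>(s["W_ctx_r"]);
  n.W12_l = as<mat>(s["W_12_l"]);   n.W12_r = as<mat>(s["W_12_r"]);
  n.Wout_l = as<mat>(s["W_out_l"]); n.Wout_r = as<mat>(s["W_out_r"]);
  n.Wx1_lr = as<mat>(s["W_x1_lr"]); n.Wx1_rl = as<mat>(s["W_x1_rl"]);
  n.Wx2_lr = as<mat>(s["W_x2_lr"]); n.Wx2_rl = as<mat>(s["W_x2_rl"]);
  n.Mx1_lr = as<mat>(s["M_x1_lr"]); n.Mx1_rl = as<mat>(s["M_x1_rl"]);
  n.Mx2_lr = as<mat>(s["M_x2_lr"]); n.Mx2_rl = as<mat>(s["M_x2_rl"]);
  n.b_l1 = as<rowvec>(s["b_l1"]); n.b_r1 = as<rowvec>(s["b_r1"]);
  n.b_l2 = as<rowvec>(s["b_l2"]); n.b_r2 = as<rowvec>(s["b_r2"]);
  n.b_out = as<rowvec>(s["b_out"]);
  n.alive_l1 = as<rowvec>(s["alive_l1"]); n.alive_r1 = as<rowvec>(s["alive_r1"]);
  n.alive_l2 = as<rowvec>(s["alive_l2"]); n.alive_r2 = as<rowvec>(s["alive_r2"]);
  vec g = as<vec>(s["gain"]);
  n.g_l1 = g(0); n.g_r1 = g(1); n.g_l2 = g(2); n.g_r2 = g(3);
  n.neg_only = as<int>(s["neg_only"]) != 0;
  n.nio = n.Win_l.n_rows; n.nL = n.Win_l.n_cols; n.nR = n.Win_r.n_cols;
  return n;
}

List export_weights(const Net& n) {
  return List::create(
    _["W_in_l"] = n.Win_l, _["W_in_r"] = n.Win_r,
    _["W_ctx_l"] = n.Wctx_l, _["W_ctx_r"] = n.Wctx_r,
    _["W_12_l"] = n.W12_l, _["W_12_r"] = n.W12_r,
    _["W_out_l"] = n.Wout_l, _["W_out_r"] = n.Wout_r,
    _["W_x1_lr"] = n.Wx1_lr, _["W_x1_rl"] = n.Wx1_rl,
    _["W_x2_lr"] = n.Wx2_lr, _["W_x2_rl"] = n.Wx2_rl,
    _["b_l1"] = n.b_l1, _["b_r1"] = n.b_r1,
    _["b_l2"] = n.b_l2, _["b_r2"] = n.b_r2, _["b_out"] = n.b_out);
}

// activation = logistic(g * net), masked by the alive vector
inline void squash(rowvec& a, const rowvec& net, double g,
                   const rowvec& alive) {
  const arma::uword n = net.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    a[i] = alive[i] / (1.0 + std::exp(-g * net[i]));
}

struct Grads {
  mat Win_l, Win_r, Wctx_l, Wctx_r, W12_l, W12_r, Wout_l, Wout_r;
  mat Wx1_lr, Wx1_rl, Wx2_lr, Wx2_rl;
  rowvec b_l1, b_r1, b_l2, b_r2, b_out;
  void init(const Net& n) {
    Win_l.zeros(n.nio, n.nL); Win_r.zeros(n.nio, n.nR);
    Wctx_l.zeros(n.nL, n.nL); Wctx_r.zeros(n.nR, n.nR);
    W12_l.zeros(n.nL, n.nL);  W12_r.zeros(n.nR, n.nR);
    Wout_l.zeros(n.nL, n.nio); Wout_r.zeros(n.nR, n.nio);
    Wx1_lr.zeros(n.nL, n.nR); Wx1_rl.zeros(n.nR, n.nL);
    Wx2_lr.zeros(n.nL, n.nR); Wx2_rl.zeros(n.nR, n.nL);
    b_l1.zeros(n.nL); b_r1.zeros(n.nR);
    b_l2.zeros(n.nL); b_r2.zeros(n.nR); b_out.zeros(n.nio);
  }
};

// per-trial activations, deltas and scratch vectors, allocated once
struct Workspace {
  mat A_l1, A_r1, A_l2, A_r2, A_out;   // N_TICKS x n
  mat D_l1, D_r1, D_l2, D_r2;
  rowvec x, net, a_l1, a_r1, a_l2, a_r2;
  rowvec p_l1, p_r1, p_l2, p_r2;
  rowvec d_out, e_1, e_2, d_l1, d_r1, d_l2, d_r2;
  Grads g;
  void init(const Net& n) {
    A_l1.set_size(N_TICKS, n.nL); A_r1.set_size(N_TICKS, n.nR);
    A_l2.set_size(N_TICKS, n.nL); A_r2.set_size(N_TICKS, n.nR);
    A_out.set_size(N_TICKS, n.nio);
    D_l1.set_size(N_TICKS, n.nL); D_r1.set_size(N_TICKS, n.nR);
    D_l2.set_size(N_TICKS, n.nL); D_r2.set_size(N_TICKS, n.nR);
    x.set_size(n.nio); net.set_size(std::max(n.nL, std::max(n.nR, n.nio)));
    a_l1.set_size(n.nL); a_r1.set_size(n.nR);
    a_l2.set_size(n.nL); a_r2.set_size(n.nR);
    p_l1.set_size(n.nL); p_r1.set_size(n.nR);
    p_l2.set_size(n.nL); p_r2.set_size(n.nR);
    d_out.set_size(n.nio);
    e_1.set_size(std::max(n.nL, n.nR)); e_2.set_size(std::max(n.nL, n.nR));
    d_l1.set_size(n.nL); d_r1.set_size(n.nR);
    d_l2.set_size(n.nL); d_r2.set_size(n.nR);
    g.init(n);
  }
};

// One six-tick trial into ws.A_*. feats is items x (3*nio); the trial uses
// row `item`. silence: 0 none, 1 left, 2 right (zeroes that side's
// input->H1 contribution).
void forward(const Net& n, const mat& feats_all, int item, int silence,
             Workspace& ws) {
  ws.p_l1.zeros(); ws.p_r1.zeros(); ws.p_l2.zeros(); ws.p_r2.zeros();
  for (int t = 0; t < N_TICKS; ++t) {
    if (t < N_SLOTS)
      ws.x = feats_all.submat(item, t * n.nio, item, (t + 1) * n.nio - 1);
    else
      ws.x.zeros();
    rowvec net_l1(ws.net.memptr(), n.nL, false, true);
    net_l1 = n.b_l1;
    if (silence != 1) net_l1 += ws.x * n.Win_l;
    net_l1 += ws.p_l1 * n.Wctx_l;
    if (n.nR > 0) net_l1 += ws.p_r1 * n.Wx1_rl;
    squash(ws.a_l1, net_l1, n.g_l1, n.alive_l1);
    rowvec net_r1(ws.net.memptr(), n.nR, false, true);
    net_r1 = n.b_r1;
    if (silence != 2) net_r1 += ws.x * n.Win_r;
    net_r1 += ws.p_r1 * n.Wctx_r;
    if (n.nL > 0) net_r1 += ws.p_l1 * n.Wx1_lr;
    squash(ws.a_r1, net_r1, n.g_r1, n.alive_r1);
    rowvec net_l2(ws.net.memptr(), n.nL, false, true);
    net_l2 = n.b_l2;
    net_l2 += ws.a_l1 * n.W12_l;
    if (n.nR > 0) net_l2 += ws.p_r2 * n.Wx2_rl;
    squash(ws.a_l2, net_l2, n.g_l2, n.alive_l2);
    rowvec net_r2(ws.net.memptr(), n.nR, false, true);
    net_r2 = n.b_r2;
    net_r2 += ws.a_r1 * n.W12_r;
    if (n.nL > 0) net_r2 += ws.p_l2 * n.Wx2_lr;
    squash(ws.a_r2, net_r2, n.g_r2, n.alive_r2);
    rowvec net_out(ws.net.memptr(), n.nio, false, true);
    net_out = n.b_out;
    net_out += ws.a_l2 * n.Wout_l;
    net_out += ws.a_r2 * n.Wout_r;
    for (int k = 0; k < n.nio; ++k)
      ws.A_out(t, k) = 1.0 / (1.0 + std::exp(-net_out[k]));
    ws.A_l1.row(t) = ws.a_l1; ws.A_r1.row(t) = ws.a_r1;
    ws.A_l2.row(t) = ws.a_l2; ws.A_r2.row(t) = ws.a_r2;
    ws.p_l1 = ws.a_l1; ws.p_r1 = ws.a_r1;
    ws.p_l2 = ws.a_l2; ws.p_r2 = ws.a_r2;
  }
}

double trial_loss(const Workspace& ws, const mat& feats_all, int item,
                  int nio) {
  double loss = 0.0;
  for (int t = N_SLOTS; t < N_TICKS; ++t) {
    for (int k = 0; k < nio; ++k) {
      double a = std::min(std::max(ws.A_out(t, k), 1e-12), 1.0 - 1e-12);
      double tau = feats_all(item, (t - N_SLOTS) * nio + k);
      loss -= tau * std::log(a) + (1.0 - tau) * std::log(1.0 - a);
    }
  }
  return loss;
}

// Backpropagation over one trial; gradients accumulate into ws.g (zeroed
// here). With truncated = true the Elman context and the one-tick-delayed
// cross inputs are treated as constants, so no error crosses the tick
// boundary; otherwise full backprop through time within the trial.
void backward(const Net& n, const mat& feats_all, int item, bool truncated,
              Workspace& ws) {
  ws.g.init(n);
  for (int t = N_TICKS - 1; t >= 0; --t) {
    if (t >= N_SLOTS) {
      for (int k = 0; k < n.nio; ++k)
        ws.d_out[k] = ws.A_out(t, k) -
          feats_all(item, (t - N_SLOTS) * n.nio + k);
    } else {
      ws.d_out.zeros();
    }

    rowvec e_l2(ws.e_1.memptr(), n.nL, false, true);
    e_l2 = ws.d_out * n.Wout_l.t();
    rowvec e_r2(ws.e_2.memptr(), n.nR, false, true);
    e_r2 = ws.d_out * n.Wout_r.t();
    if (!truncated && t + 1 < N_TICKS) {
      if (n.nR > 0) e_l2 += ws.D_r2.row(t + 1) * n.Wx2_lr.t();
      if (n.nL > 0) e_r2 += ws.D_l2.row(t + 1) * n.Wx2_rl.t();
    }
    for (int i = 0; i < n.nL; ++i) {
      double a = ws.A_l2(t, i);
      ws.d_l2[i] = e_l2[i] * n.g_l2 * a * (1.0 - a) * n.alive_l2[i];
    }
    for (int i = 0; i < n.nR; ++i) {
      double a = ws.A_r2(t, i);
      ws.d_r2[i] = e_r2[i] * n.g_r2 * a * (1.0 - a) * n.alive_r2[i];
    }
    ws.D_l2.row(t) = ws.d_l2; ws.D_r2.row(t) = ws.d_r2;

    rowvec e_l1(ws.e_1.memptr(), n.nL, false, true);
    e_l1 = ws.d_l2 * n.W12_l.t();
    rowvec e_r1(ws.e_2.memptr(), n.nR, false, true);
    e_r1 = ws.d_r2 * n.W12_r.t();
    if (!truncated && t + 1 < N_TICKS) {
      e_l1 += ws.D_l1.row(t + 1) * n.Wctx_l.t();
      e_r1 += ws.D_r1.row(t + 1) * n.Wctx_r.t();
      if (n.nR > 0) e_l1 += ws.D_r1.row(t + 1) * n.Wx1_lr.t();
      if (n.nL > 0) e_r1 += ws.D_l1.row(t + 1) * n.Wx1_rl.t();
    }
    for (int i = 0; i < n.nL; ++i) {
      double a = ws.A_l1(t, i);
      ws.d_l1[i] = e_l1[i] * n.g_l1 * a * (1.0 - a) * n.alive_l1[i];
    }
    for (int i = 0; i < n.nR; ++i) {
      double a = ws.A_r1(t, i);
      ws.d_r1[i] = e_r1[i] * n.g_r1 * a * (1.0 - a) * n.alive_r1[i];
    }
    ws.D_l1.row(t) = ws.d_l1; ws.D_r1.row(t) = ws.d_r1;

    if (t < N_SLOTS)
      ws.x = feats_all.submat(item, t * n.nio, item, (t + 1) * n.nio - 1);
    else
      ws.x.zeros();
    ws.g.Wout_l += ws.A_l2.row(t).t() * ws.d_out;
    ws.g.Wout_r += ws.A_r2.row(t).t() * ws.d_out;
    ws.g.b_out += ws.d_out;
    ws.g.W12_l += ws.A_l1.row(t).t() * ws.d_l2;
    ws.g.W12_r += ws.A_r1.row(t).t() * ws.d_r2;
    ws.g.b_l2 += ws.d_l2; ws.g.b_r2 += ws.d_r2;
    if (t < N_SLOTS) {
      ws.g.Win_l += ws.x.t() * ws.d_l1;
      ws.g.Win_r += ws.x.t() * ws.d_r1;
    }
    ws.g.b_l1 += ws.d_l1; ws.g.b_r1 += ws.d_r1;
    if (t > 0) {
      ws.g.Wctx_l += ws.A_l1.row(t - 1).t() * ws.d_l1;
      ws.g.Wctx_r += ws.A_r1.row(t - 1).t() * ws.d_r1;
      ws.g.Wx1_lr += ws.A_l1.row(t - 1).t() * ws.d_r1;
      ws.g.Wx1_rl += ws.A_r1.row(t - 1).t() * ws.d_l1;
      ws.g.Wx2_lr += ws.A_l2.row(t - 1).t() * ws.d_r2;
      ws.g.Wx2_rl += ws.A_r2.row(t - 1).t() * ws.d_l2;
    }
  }
}

void apply_update(Net& n, const Grads& g, double lr) {
  n.Win_l -= lr * g.Win_l; n.Win_r -= lr * g.Win_r;
  n.Wctx_l -= lr * g.Wctx_l; n.Wctx_r -= lr * g.Wctx_r;
  n.W12_l -= lr * g.W12_l; n.W12_r -= lr * g.W12_r;
  n.Wout_l -= lr * g.Wout_l; n.Wout_r -= lr * g.Wout_r;
  n.b_l1 -= lr * g.b_l1; n.b_r1 -= lr * g.b_r1;
  n.b_l2 -= lr * g.b_l2; n.b_r2 -= lr * g.b_r2;
  n.b_out -= lr * g.b_out;
  // cross blocks: honour the sparsity mask, and the sign constraint if any
  n.Wx1_lr -= lr * g.Wx1_lr; n.Wx1_lr %= n.Mx1_lr;
  n.Wx1_rl -= lr * g.Wx1_rl; n.Wx1_rl %= n.Mx1_rl;
  n.Wx2_lr -= lr * g.Wx2_lr; n.Wx2_lr %= n.Mx2_lr;
  n.Wx2_rl -= lr * g.Wx2_rl; n.Wx2_rl %= n.Mx2_rl;
  if (n.neg_only) {
    n.Wx1_lr.transform([](double w) { return w > 0.0 ? 0.0 : w; });
    n.Wx1_rl.transform([](double w) { return w > 0.0 ? 0.0 : w; });
    n.Wx2_lr.transform([](double w) { return w > 0.0 ? 0.0 : w; });
    n.Wx2_rl.transform([](double w) { return w > 0.0 ? 0.0 : w; });
  }
}

List grads_to_list(const Grads& g, double loss) {
  return List::create(
    _["loss"] = loss,
    _["W_in_l"] = g.Win_l, _["W_in_r"] = g.Win_r,
    _["W_ctx_l"] = g.Wctx_l, _["W_ctx_r"] = g.Wctx_r,
    _["W_12_l"] = g.W12_l, _["W_12_r"] = g.W12_r,
    _["W_out_l"] = g.Wout_l, _["W_out_r"] = g.Wout_r,
    _["W_x1_lr"] = g.Wx1_lr, _["W_x1_rl"] = g.Wx1_rl,
    _["W_x2_lr"] = g.Wx2_lr, _["W_x2_rl"] = g.Wx2_rl,
    _["b_l1"] = g.b_l1, _["b_r1"] = g.b_r1,
    _["b_l2"] = g.b_l2, _["b_r2"] = g.b_r2, _["b_out"] = g.b_out);
}

void check_feats(const Net& n, const mat& feats_all) {
  if ((int)feats_all.n_cols != N_SLOTS * n.nio)
    stop("encoded items must have 3 * n_io columns");
}

}  // namespace

// [[Rcpp::export(name = ".srn_forward_cpp")]]
List srn_forward_cpp(List state, arma::mat feats, int silence) {
  Net n = load_net(state);
  if ((int)feats.n_rows != N_SLOTS || (int)feats.n_cols != n.nio)
    stop("features must be a 3 x %d matrix", n.nio);
  Workspace ws; ws.init(n);
  mat frow = arma::reshape(feats.t(), 1, N_SLOTS * n.nio);
  forward(n, frow, 0, silence, ws);
  return List::create(_["l1"] = ws.A_l1, _["r1"] = ws.A_r1,
                      _["l2"] = ws.A_l2, _["r2"] = ws.A_r2,
                      _["out"] = ws.A_out);
}

// [[Rcpp::export(name = ".srn_loss_cpp")]]
double srn_loss_cpp(List state, arma::mat feats) {
  Net n = load_net(state);
  Workspace ws; ws.init(n);
  mat frow = arma::reshape(feats.t(), 1, N_SLOTS * n.nio);
  forward(n, frow, 0, 0, ws);
  return trial_loss(ws, frow, 0, n.nio);
}

// [[Rcpp::export(name = ".srn_grads_cpp")]]
List srn_grads_cpp(List state, arma::mat feats, bool truncated) {
  Net n = load_net(state);
  Workspace ws; ws.init(n);
  mat frow = arma::reshape(feats.t(), 1, N_SLOTS * n.nio);
  forward(n, frow, 0, 0, ws);
  backward(n, frow, 0, truncated, ws);
  return grads_to_list(ws.g, trial_loss(ws, frow, 0, n.nio));
}

// [[Rcpp::export(name = ".srn_train_step_cpp")]]
List srn_train_step_cpp(List state, arma::mat feats, double lr,
                        bool truncated) {
  Net n = load_net(state);
  Workspace ws; ws.init(n);
  mat frow = arma::reshape(feats.t(), 1, N_SLOTS * n.nio);
  forward(n, frow, 0, 0, ws);
  backward(n, frow, 0, truncated, ws);
  double loss = trial_loss(ws, frow, 0, n.nio);
  apply_update(n, ws.g, lr);
  return List::create(_["weights"] = export_weights(n), _["loss"] = loss);
}

// Train for n_pres presentations, sampling items from the cumulative
// presentation distribution using R's RNG (so set.seed() governs the
// presentation sequence). Returns updated weights and the mean loss.
// [[Rcpp::export(name = ".srn_train_chunk_cpp")]]
List srn_train_chunk_cpp(List state, arma::mat feats_all, arma::vec cumprobs,
                         int n_pres, double lr, bool truncated) {
  Net n = load_net(state);
  check_feats(n, feats_all);
  Workspace ws; ws.init(n);
  double loss_sum = 0.0;
  int n_items = feats_all.n_rows;
  for (int p = 0; p < n_pres; ++p) {
    double u = R::unif_rand();
    int item = std::lower_bound(cumprobs.begin(), cumprobs.end(), u) -
      cumprobs.begin();
    if (item >= n_items) item = n_items - 1;
    forward(n, feats_all, item, 0, ws);
    backward(n, feats_all, item, truncated, ws);
    loss_sum += trial_loss(ws, feats_all, item, n.nio);
    apply_update(n, ws.g, lr);
  }
  return List::create(_["weights"] = export_weights(n),
                      _["mean_loss"] = n_pres > 0 ? loss_sum / n_pres
                                                  : NA_REAL);
}

// Forward-run a batch of items without learning; returns per-layer
// activation matrices with the six ticks concatenated per row.
// [[Rcpp::export(name = ".srn_run_items_cpp")]]
List srn_run_items_cpp(List state, arma::mat feats_all, int silence) {
  Net n = load_net(state);
  check_feats(n, feats_all);
  Workspace ws; ws.init(n);
  int n_items = feats_all.n_rows;
  mat out(n_items, N_TICKS * n.nio), l1(n_items, N_TICKS * n.nL),
      r1(n_items, N_TICKS * n.nR), l2(n_items, N_TICKS * n.nL),
      r2(n_items, N_TICKS * n.nR);
  for (int i = 0; i < n_items; ++i) {
    forward(n, feats_all, i, silence, ws);
    out.row(i) = arma::vectorise(ws.A_out, 1);
    l1.row(i) = arma::vectorise(ws.A_l1, 1);
    r1.row(i) = arma::vectorise(ws.A_r1, 1);
    l2.row(i) = arma::vectorise(ws.A_l2, 1);
    r2.row(i) = arma::vectorise(ws.A_r2, 1);
  }
  return List::create(_["out"] = out, _["l1"] = l1, _["r1"] = r1,
                      _["l2"] = l2, _["r2"] = r2);
}
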