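// Core numerics for the S-CTRNN with parametric bias: forward dynamics,
// heteroscedastic negative log-likelihood, exact BPTT gradients (open- and
// closed-loop), full-batch gradient-descent-with-momentum training, and the
// sliding-window PB error regression used during online adaptation.
//
// Conventions: matrices are unit-major (rows = receiving units), sequences
// are time-major (rows = time steps). Context internal states start from a
// caller-supplied vector (zero at sequence/trial starts). PB internal states
// are constant across a forward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// exp-argument cap for the variance units: keeps v finite (<= ~1e13 + eps)
// while preserving the divergent error dynamics at extreme K.
static const double EXP_CAP = 30.0;

namespace {

struct Net {
  mat W_xc;  // n_context x n_input
  mat W_cc;  // n_context x n_context
  mat W_pc;  // n_context x n_pb
  mat W_co;  // n_output x n_context
  mat W_cv;  // n_variance x n_context
  vec b_c, b_o, b_v;
  double tau, K, eps;
  int Ni, Nc, Np, No, Nv;
};

Net as_net(const Rcpp::List& params, double tau, double K, double eps) {
  Net n;
  n.W_xc = Rcpp::as<mat>(params["W_xc"]);
  n.W_cc = Rcpp::as<mat>(params["W_cc"]);
  n.W_pc = Rcpp::as<mat>(params["W_pc"]);
  n.W_co = Rcpp::as<mat>(params["W_co"]);
  n.W_cv = Rcpp::as<mat>(params["W_cv"]);
  n.b_c  = Rcpp::as<vec>(params["b_c"]);
  n.b_o  = Rcpp::as<vec>(params["b_o"]);
  n.b_v  = Rcpp::as<vec>(params["b_v"]);
  n.tau = tau; n.K = K; n.eps = eps;
  n.Ni = n.W_xc.n_cols; n.Nc = n.W_xc.n_rows; n.Np = n.W_pc.n_cols;
  n.No = n.W_co.n_rows; n.Nv = n.W_cv.n_rows;
  return n;
}

struct Grads {
  mat W_xc, W_cc, W_pc, W_co, W_cv;
  vec b_c, b_o, b_v, u_pb;
  // pb_only skips the weight/bias buffers entirely (hot path of the
  // online regression)
  void zeros_like(const Net& n, bool pb_only = false) {
    u_pb.zeros(n.Np);
    if (pb_only) return;
    W_xc.zeros(n.Nc, n.Ni); W_cc.zeros(n.Nc, n.Nc); W_pc.zeros(n.Nc, n.Np);
    W_co.zeros(n.No, n.Nc); W_cv.zeros(n.Nv, n.Nc);
    b_c.zeros(n.Nc); b_o.zeros(n.No); b_v.zeros(n.Nv);
  }
};

// unit-major (columns = time steps) for contiguous access in the loops;
// transposed to the R-facing time-major layout only at the API boundary
struct Fwd {
  mat X;   // realized inputs, Ni x T
  mat Uc;  // context internal states, Nc x T
  mat C;   // context activations, Nc x T
  mat Y;   // mean predictions, No x T
  mat V;   // variance predictions, Nv x T
};

// hand-rolled small-matrix kernels: armadillo dispatches even tiny
// products to BLAS, whose call overhead dominates at these sizes
// out += A x  (A column-major)
inline void gemv_acc(const mat& A, const double* x, double* out) {
  const uword m = A.n_rows, n = A.n_cols;
  for (uword j = 0; j < n; ++j) {
    const double xj = x[j];
    const double* col = A.colptr(j);
    for (uword i = 0; i < m; ++i) out[i] += col[i] * xj;
  }
}

// out = A' x
inline void gemtv(const mat& A, const double* x, double* out) {
  const uword m = A.n_rows, n = A.n_cols;
  for (uword j = 0; j < n; ++j) {
    const double* col = A.colptr(j);
    double acc = 0.0;
    for (uword i = 0; i < m; ++i) acc += col[i] * x[i];
    out[j] = acc;
  }
}

inline vec variance_activation(const vec& u_v, double K, double eps) {
  vec a = clamp(u_v + K, -datum::inf, EXP_CAP);
  return exp(a) + eps;
}

// One integration step: updates u_c in place, returns (c, y, v, u_v) via refs.
struct StepWs { vec drive, u_o, u_v; };

inline void step_units(const Net& net, const vec& x, const vec& p,
                       vec& u_c, vec& c_prev, vec& c, vec& y, vec& v,
                       StepWs& ws) {
  vec& drive = ws.drive; drive = net.b_c;
  gemv_acc(net.W_xc, x.memptr(), drive.memptr());
  gemv_acc(net.W_cc, c_prev.memptr(), drive.memptr());
  gemv_acc(net.W_pc, p.memptr(), drive.memptr());
  const double leak = 1.0 - 1.0 / net.tau;
  for (int i = 0; i < net.Nc; ++i) {
    u_c[i] = drive[i] / net.tau + leak * u_c[i];
    c[i] = std::tanh(u_c[i]);
  }
  vec& u_o = ws.u_o; u_o = net.b_o;
  gemv_acc(net.W_co, c.memptr(), u_o.memptr());
  for (int i = 0; i < net.No; ++i) y[i] = std::tanh(u_o[i]);
  vec& u_v = ws.u_v; u_v = net.b_v;
  gemv_acc(net.W_cv, c.memptr(), u_v.memptr());
  for (int i = 0; i < net.Nv; ++i)
    v[i] = std::exp(std::min(u_v[i] + net.K, EXP_CAP)) + net.eps;
}

// Forward pass. If closed_loop, only X.row(0) is used as an external input;
// later inputs are the previous step's mean predictions.
// X_in arrives in the R-facing layout (T x Ni rows = time steps)
Fwd forward(const Net& net, const mat& X_in, const vec& u_pb, const vec& uc0,
            bool closed_loop, int T) {
  Fwd f;
  f.X.set_size(net.Ni, T); f.Uc.set_size(net.Nc, T); f.C.set_size(net.Nc, T);
  f.Y.set_size(net.No, T); f.V.set_size(net.Nv, T);
  vec p = tanh(u_pb);
  vec u_c = uc0, c_prev = tanh(uc0), c(net.Nc), y(net.No), v(net.Nv);
  vec x = X_in.row(0).t();
  StepWs ws;
  for (int t = 0; t < T; ++t) {
    if (t > 0) x = closed_loop ? y : X_in.row(t).t();
    step_units(net, x, p, u_c, c_prev, c, y, v, ws);
    f.X.col(t) = x; f.Uc.col(t) = u_c; f.C.col(t) = c;
    f.Y.col(t) = y; f.V.col(t) = v;
    c_prev = c;
  }
  return f;
}

// Y/V unit-major (N x T); targets in the R layout (T x N)
double nll_masked(const mat& Y, const mat& V, const mat& targets,
                  const uvec& dims) {
  double L = 0.0;
  for (uword t = 0; t < Y.n_cols; ++t)
    for (uword k = 0; k < dims.n_elem; ++k) {
      uword i = dims[k];
      double e = targets(t, i) - Y(i, t), v = V(i, t);
      L += 0.5 * std::log(2.0 * datum::pi * v) + e * e / (2.0 * v);
    }
  return L;
}

// Exact reverse-mode gradient of the masked NLL for one sequence.
// Closed-loop passes propagate the gradient through the prediction->input
// feedback path. pb_only skips the weight/bias accumulators.
double backward(const Net& net, const Fwd& f, const mat& targets,
                const uvec& dims, const vec& u_pb, const vec& uc0,
                bool closed_loop, bool pb_only, Grads& g) {
  const int T = f.Y.n_cols;
  vec p = tanh(u_pb);
  vec delta(net.Nc, fill::zeros);       // dL/du_c at t+1
  vec c0 = tanh(uc0);
  double loss = 0.0;
  // per-step sensitivities, accumulated into weight gradients by single
  // GEMMs after the time loop
  mat G_o(net.No, T), G_v(net.Nv, T), D(net.Nc, T);
  vec dLdy(net.No), g_v(net.Nv), fb(net.No), g_o(net.No);
  vec dLdc(net.Nc), tmp(net.Nc), d_t(net.Nc);
  for (int t = T - 1; t >= 0; --t) {
    const vec& y = f.Y.unsafe_col(t);
    const vec& v = f.V.unsafe_col(t);
    const vec& c = f.C.unsafe_col(t);
    dLdy.zeros(); g_v.zeros();
    for (uword k = 0; k < dims.n_elem; ++k) {
      uword i = dims[k];
      double e = targets(t, i) - y[i];
      loss += 0.5 * std::log(2.0 * datum::pi * v[i]) + e * e / (2.0 * v[i]);
      dLdy[i] = -e / v[i];
      // d/du exp(u+K) = v - eps; kept past the overflow cap so that the
      // log-volume term can pull saturated variance units back down
      double dvdu = v[i] - net.eps;
      g_v[i] = (0.5 / v[i] - e * e / (2.0 * v[i] * v[i])) * dvdu;
    }
    if (closed_loop && t < T - 1) {
      gemtv(net.W_xc, delta.memptr(), fb.memptr());  // x_{t+1} = y_t
      dLdy += fb / net.tau;
    }
    g_o = dLdy % (1.0 - y % y);
    gemtv(net.W_co, g_o.memptr(), dLdc.memptr());
    gemtv(net.W_cv, g_v.memptr(), tmp.memptr());
    dLdc += tmp;
    gemtv(net.W_cc, delta.memptr(), tmp.memptr());
    dLdc += tmp / net.tau;
    d_t = dLdc % (1.0 - c % c) + (1.0 - 1.0 / net.tau) * delta;
    G_o.col(t) = g_o; G_v.col(t) = g_v; D.col(t) = d_t;
    delta = d_t;
  }
  vec d_sum = sum(D, 1);
  if (!pb_only) {
    // c_{t-1} columns: c0 followed by c_0 .. c_{T-2}
    mat Cprev(net.Nc, T);
    Cprev.col(0) = c0;
    if (T > 1) Cprev.cols(1, T - 1) = f.C.cols(0, T - 2);
    g.W_co += G_o * f.C.t();  g.b_o += sum(G_o, 1);
    g.W_cv += G_v * f.C.t();  g.b_v += sum(G_v, 1);
    g.W_xc += (D * f.X.t()) / net.tau;
    g.W_cc += (D * Cprev.t()) / net.tau;
    g.W_pc += (d_sum / net.tau) * p.t();
    g.b_c  += d_sum / net.tau;
  }
  g.u_pb += (net.W_pc.t() * d_sum / net.tau) % (1.0 - p % p);
  return loss;
}

Rcpp::List fwd_to_list(const Fwd& f) {
  return Rcpp::List::create(
      Rcpp::Named("X") = mat(f.X.t()), Rcpp::Named("Uc") = mat(f.Uc.t()),
      Rcpp::Named("C") = mat(f.C.t()), Rcpp::Named("Y") = mat(f.Y.t()),
      Rcpp::Named("V") = mat(f.V.t()));
}

uvec dims_to_uvec(const Rcpp::IntegerVector& dims) {
  uvec d(dims.size());
  for (int k = 0; k < dims.size(); ++k) d[k] = dims[k] - 1;  // R 1-based
  return d;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_forward(const Rcpp::List& params, const arma::mat& X,
                       const arma::vec& u_pb, const arma::vec& uc0,
                       double tau, double K, double eps, bool closed_loop,
                       int T) {
  Net net = as_net(params, tau, K, eps);
  if ((int)X.n_cols != net.Ni)
    Rcpp::stop("input has %d columns; network expects %d", X.n_cols, net.Ni);
  Fwd f = forward(net, X, u_pb, uc0, closed_loop, T);
  return fwd_to_list(f);
}

// [[Rcpp::export]]
double cpp_sequence_nll(const Rcpp::List& params, const arma::mat& X,
                        const arma::mat& targets, const arma::vec& u_pb,
                        const arma::vec& uc0, double tau, double K,
                        double eps, const Rcpp::IntegerVector& dims,
                        bool closed_loop) {
  Net net = as_net(params, tau, K, eps);
  Fwd f = forward(net, X, u_pb, uc0, closed_loop, targets.n_rows);
  return nll_masked(f.Y, f.V, targets, dims_to_uvec(dims));
}

// [[Rcpp::export]]
Rcpp::List cpp_bptt(const Rcpp::List& params, const arma::mat& X,
                    const arma::mat& targets, const arma::vec& u_pb,
                    const arma::vec& uc0, double tau, double K, double eps,
                    const Rcpp::IntegerVector& dims, bool closed_loop,
                    bool pb_only) {
  Net net = as_net(params, tau, K, eps);
  Fwd f = forward(net, X, u_pb, uc0, closed_loop, targets.n_rows);
  Grads g; g.zeros_like(net, pb_only);
  double loss = backward(net, f, targets, dims_to_uvec(dims), u_pb, uc0,
                         closed_loop, pb_only, g);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("W_xc") = g.W_xc, Rcpp::Named("W_cc") = g.W_cc,
      Rcpp::Named("W_pc") = g.W_pc, Rcpp::Named("W_co") = g.W_co,
      Rcpp::Named("W_cv") = g.W_cv, Rcpp::Named("b_c") = g.b_c,
      Rcpp::Named("b_o") = g.b_o, Rcpp::Named("b_v") = g.b_v,
      Rcpp::Named("u_pb") = g.u_pb);
}

// Full-batch offline learning: one gradient step per epoch on the NLL summed
// over all sequences, all requested dims; per-sequence PB initial internal
// states carry their own gradients and momentum buffers.
// [[Rcpp::export]]
Rcpp::List cpp_train(const Rcpp::List& params, const Rcpp::List& X_list,
                     const Rcpp::List& target_list, const arma::mat& u0_pb,
                     double tau, double K, double eps,
                     const Rcpp::IntegerVector& dims, double alpha,
                     double eta, int epochs, bool closed_loop,
                     double grad_scale) {
  Net net = as_net(params, tau, K, eps);
  const int S = X_list.size();
  uvec dmask = dims_to_uvec(dims);
  std::vector<mat> Xs(S), Ts(S);
  for (int s = 0; s < S; ++s) {
    Xs[s] = Rcpp::as<mat>(X_list[s]);
    Ts[s] = Rcpp::as<mat>(target_list[s]);
  }
  mat pb = u0_pb;                     // Np x S
  Grads mom; mom.zeros_like(net);     // momentum buffers persist over epochs
  mat pb_mom(pb.n_rows, S, fill::zeros);
  vec uc0(net.Nc, fill::zeros);
  vec loss_hist(epochs, fill::zeros);
  Net best = net; mat best_pb = pb;   // lowest-loss checkpoint
  double best_loss = datum::inf; int best_epoch = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    Grads g; g.zeros_like(net);
    mat pb_g(pb.n_rows, S, fill::zeros);
    double loss = 0.0;
    for (int s = 0; s < S; ++s) {
      Fwd f = forward(net, Xs[s], pb.col(s), uc0, closed_loop,
                      Ts[s].n_rows);
      Grads gs; gs.zeros_like(net);
      loss += backward(net, f, Ts[s], dmask, pb.col(s), uc0, closed_loop,
                       false, gs);
      g.W_xc += gs.W_xc; g.W_cc += gs.W_cc; g.W_pc += gs.W_pc;
      g.W_co += gs.W_co; g.W_cv += gs.W_cv;
      g.b_c += gs.b_c; g.b_o += gs.b_o; g.b_v += gs.b_v;
      pb_g.col(s) = gs.u_pb;
    }
    if (!std::isfinite(loss))
      Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
    loss_hist[ep] = loss;
    if (loss < best_loss) {
      best_loss = loss; best_epoch = ep + 1;
      best = net; best_pb = pb;
    }
    // time-normalized gradient (see train_offline): the learning rate
    // applies per time step, keeping the update scale-invariant in T
    const double alpha_eff = alpha * grad_scale;
    // gradient descent with momentum (delta = -alpha*g + eta*delta)
    mom.W_xc = -alpha_eff * g.W_xc + eta * mom.W_xc;  net.W_xc += mom.W_xc;
    mom.W_cc = -alpha_eff * g.W_cc + eta * mom.W_cc;  net.W_cc += mom.W_cc;
    mom.W_pc = -alpha_eff * g.W_pc + eta * mom.W_pc;  net.W_pc += mom.W_pc;
    mom.W_co = -alpha_eff * g.W_co + eta * mom.W_co;  net.W_co += mom.W_co;
    mom.W_cv = -alpha_eff * g.W_cv + eta * mom.W_cv;  net.W_cv += mom.W_cv;
    mom.b_c  = -alpha_eff * g.b_c  + eta * mom.b_c;   net.b_c  += mom.b_c;
    mom.b_o  = -alpha_eff * g.b_o  + eta * mom.b_o;   net.b_o  += mom.b_o;
    mom.b_v  = -alpha_eff * g.b_v  + eta * mom.b_v;   net.b_v  += mom.b_v;
    pb_mom = -alpha_eff * pb_g + eta * pb_mom;        pb += pb_mom;
    if (ep % 200 == 0) Rcpp::checkUserInterrupt();
  }
  auto pack = [](const Net& n) {
    return Rcpp::List::create(
        Rcpp::Named("W_xc") = n.W_xc, Rcpp::Named("W_cc") = n.W_cc,
        Rcpp::Named("W_pc") = n.W_pc, Rcpp::Named("W_co") = n.W_co,
        Rcpp::Named("W_cv") = n.W_cv, Rcpp::Named("b_c") = n.b_c,
        Rcpp::Named("b_o") = n.b_o, Rcpp::Named("b_v") = n.b_v);
  };
  return Rcpp::List::create(
      Rcpp::Named("params") = pack(net),
      Rcpp::Named("u0_pb") = pb,
      Rcpp::Named("best_params") = pack(best),
      Rcpp::Named("best_u0_pb") = best_pb,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("loss_history") = loss_hist);
}

// One environment step's worth of postdiction: n_iters cycles of
// closed-loop window regeneration, PB-only BPTT on the windowed NLL, and a
// momentum gradient update of the PB internal state; then a final
// regeneration plus a one-step-ahead prediction from the last window state.
// [[Rcpp::export]]
Rcpp::List cpp_regress_window(const Rcpp::List& params, const arma::vec& u_pb,
                              const arma::vec& momentum, const arma::vec& uc0,
                              const arma::vec& x1, const arma::mat& targets,
                              const Rcpp::IntegerVector& dims, int n_iters,
                              double alpha, double eta, double tau, double K,
                              double eps, bool feedback_grad) {
  Net net = as_net(params, tau, K, eps);
  uvec dmask = dims_to_uvec(dims);
  const int W = targets.n_rows;
  mat X1(1, net.Ni); X1.row(0) = x1.t();
  vec pb = u_pb, mom = momentum;
  double nll_pre = NA_REAL;
  // as in learning, the rate applies to the time-averaged gradient
  const double alpha_eff = alpha / W;
  for (int it = 0; it < n_iters; ++it) {
    Fwd f = forward(net, X1, pb, uc0, true, W);
    Grads g; g.zeros_like(net, true);
    double loss = backward(net, f, targets, dmask, pb, uc0,
                           feedback_grad, true, g);
    if (it == 0) nll_pre = loss;
    if (!std::isfinite(loss))
      Rcpp::stop("non-finite windowed NLL during PB regression");
    mom = -alpha_eff * g.u_pb + eta * mom;
    pb += mom;
  }
  Fwd f = forward(net, X1, pb, uc0, true, W);
  double nll_post = nll_masked(f.Y, f.V, targets, dmask);
  // one-step-ahead prediction: feed the last mean prediction back once more
  vec p = tanh(pb);
  vec u_c = f.Uc.col(W - 1), c_prev = f.C.col(W - 1);
  vec c(net.Nc), y(net.No), v(net.Nv), x = f.Y.col(W - 1);
  StepWs ws1;
  step_units(net, x, p, u_c, c_prev, c, y, v, ws1);
  return Rcpp::List::create(
      Rcpp::Named("u_pb") = pb, Rcpp::Named("momentum") = mom,
      Rcpp::Named("window") = fwd_to_list(f),
      Rcpp::Named("nll_pre") = nll_pre, Rcpp::Named("nll_post") = nll_post,
      Rcpp::Named("pred_y") = y, Rcpp::Named("pred_v") = v,
      Rcpp::Named("pred_uc") = u_c);
}
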