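// Core numerics for the biologically informed recurrent neural-mass model:
// forward rollout, closed-loop simulation, and backpropagation through time
// over a window. All randomness stays on the R side; these routines are
// deterministic functions of their arguments.
//
// State update (forward Euler, step dt, all taus in the same unit as dt):
//   I_E   = x_t + Wout %*% h_net + W_EE h_E + W_IE h_I - beta h_A
//   h_E'  = (1 - dt/tau_E) h_E + (dt/tau_E) sigmoid(I_E)
//   h_I'  = (1 - dt/tau_I) h_I + (dt/tau_I) sigmoid(W_EI h_E)
//   h_A'  = (1 - dt/tau_A) h_A + (dt/tau_A) h_E
//   h_net'= tanh(W_in x_t + W_net h_net + b_net)
// where Wout maps network k to its member parcels with per-network gain, and
// the population updates read the pre-update states (I_E uses the previous
// network state). Prediction of x_{t+1} is an affine readout of h_E'.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline vec sigmoid_vec(const vec& x) {
  return 1.0 / (1.0 + exp(-x));
}

struct StepWork {
  vec IE, sE, uI, sI, hE, hI, hA, hnet;
};

// One forward Euler step; inputs are the pre-update states.
static void birnn_step_inner(const vec& x, const vec& hE, const vec& hI,
                             const vec& hA, const vec& hnet,
                             const mat& W_EE, const mat& W_EI, const mat& W_IE,
                             const mat& W_net, const vec& b_net,
                             const vec& gain_net, const vec& aE, const vec& aI,
                             const vec& aA, double beta, const mat& W_in,
                             const uvec& net_index, StepWork& out) {
  vec gh = gain_net % hnet;        // per-network gain * network state
  vec topdown = gh.elem(net_index);  // broadcast to member parcels
  out.IE = x + topdown + W_EE * hE + W_IE * hI - beta * hA;
  out.sE = sigmoid_vec(out.IE);
  out.uI = W_EI * hE;
  out.sI = sigmoid_vec(out.uI);
  out.hE = (1.0 - aE) % hE + aE % out.sE;
  out.hI = (1.0 - aI) % hI + aI % out.sI;
  out.hA = (1.0 - aA) % hA + aA % hE;
  out.hnet = tanh(W_in * x + W_net * hnet + b_net);
}

// [[Rcpp::export]]
Rcpp::List birnn_rollout_cpp(const arma::mat& X, const arma::mat& W_EE,
                             const arma::mat& W_EI, const arma::mat& W_IE,
                             const arma::mat& W_net, const arma::vec& b_net,
                             const arma::vec& gain_net, const arma::vec& tau_E,
                             const arma::vec& tau_I, const arma::vec& tau_A,
                             double beta, const arma::vec& readout_gain,
                             const arma::vec& readout_offset,
                             const arma::mat& W_in, const arma::uvec& net_index,
                             double dt, const arma::vec& hE0,
                             const arma::vec& hI0, const arma::vec& hA0,
                             const arma::vec& hnet0, bool keep_states) {
  const uword P = X.n_rows, T = X.n_cols, K = W_net.n_rows;
  vec aE = dt / tau_E, aI = dt / tau_I, aA = dt / tau_A;
  vec hE = hE0, hI = hI0, hA = hA0, hnet = hnet0;
  mat pred(P, T - 1);
  mat HE, HI, HA, HNET;
  if (keep_states) {
    HE.set_size(P, T); HI.set_size(P, T); HA.set_size(P, T); HNET.set_size(K, T);
    HE.col(0) = hE; HI.col(0) = hI; HA.col(0) = hA; HNET.col(0) = hnet;
  }
  StepWork w;
  for (uword t = 0; t + 1 < T; ++t) {
    birnn_step_inner(X.col(t), hE, hI, hA, hnet, W_EE, W_EI, W_IE, W_net,
                     b_net, gain_net, aE, aI, aA, beta, W_in, net_index, w);
    hE = w.hE; hI = w.hI; hA = w.hA; hnet = w.hnet;
    pred.col(t) = readout_gain % hE + readout_offset;
    if (!pred.col(t).is_finite() || !hnet.is_finite()) {
      Rcpp::stop("non-finite state encountered at time index %d", (int)(t + 2));
    }
    if (keep_states) {
      HE.col(t + 1) = hE; HI.col(t + 1) = hI; HA.col(t + 1) = hA;
      HNET.col(t + 1) = hnet;
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("pred") = pred,
      Rcpp::Named("h_E") = hE, Rcpp::Named("h_I") = hI,
      Rcpp::Named("h_A") = hA, Rcpp::Named("h_net") = hnet);
  if (keep_states) {
    out["HE"] = HE; out["HI"] = HI; out["HA"] = HA; out["HNET"] = HNET;
  }
  return out;
}

// Truncated-BPTT gradient over one window. Xwin has L+1 columns: inputs are
// columns 1..L, targets columns 2..L+1. Loss is the plain MSE over P*L
// prediction errors; regularizer gradients are added on the R side.
// [[Rcpp::export]]
Rcpp::List birnn_window_grad_cpp(const arma::mat& Xwin, const arma::mat& W_EE,
                                 const arma::mat& W_EI, const arma::mat& W_IE,
                                 const arma::mat& W_net, const arma::vec& b_net,
                                 const arma::vec& gain_net,
                                 const arma::vec& tau_E, const arma::vec& tau_I,
                                 const arma::vec& tau_A, double beta,
                                 const arma::vec& readout_gain,
                                 const arma::vec& readout_offset,
                                 const arma::mat& W_in,
                                 const arma::uvec& net_index, double dt,
                                 const arma::mat& mask_EE,
                                 const arma::mat& mask_EI,
                                 const arma::mat& mask_IE,
                                 const arma::vec& hE0, const arma::vec& hI0,
                                 const arma::vec& hA0, const arma::vec& hnet0) {
  const uword P = Xwin.n_rows, L = Xwin.n_cols - 1, K = W_net.n_rows;
  vec aE = dt / tau_E, aI = dt / tau_I, aA = dt / tau_A;

  // forward pass, caching everything the backward pass needs
  mat HE(P, L + 1), HI(P, L + 1), HA(P, L + 1); mat HNET(K, L + 1);
  mat SE(P, L), SI(P, L), PRED(P, L);
  HE.col(0) = hE0; HI.col(0) = hI0; HA.col(0) = hA0; HNET.col(0) = hnet0;
  StepWork w;
  for (uword l = 0; l < L; ++l) {
    birnn_step_inner(Xwin.col(l), HE.col(l), HI.col(l), HA.col(l), HNET.col(l),
                     W_EE, W_EI, W_IE, W_net, b_net, gain_net, aE, aI, aA,
                     beta, W_in, net_index, w);
    HE.col(l + 1) = w.hE; HI.col(l + 1) = w.hI; HA.col(l + 1) = w.hA;
    HNET.col(l + 1) = w.hnet;
    SE.col(l) = w.sE; SI.col(l) = w.sI;
    PRED.col(l) = readout_gain % w.hE + readout_offset;
  }
  mat Y = Xwin.cols(1, L);
  mat R = PRED - Y;
  double loss = accu(square(R)) / (double)(P * L);
  if (!std::isfinite(loss)) Rcpp::stop("non-finite loss in BPTT window");

  // backward pass
  mat gW_EE(P, P, fill::zeros), gW_EI(P, P, fill::zeros),
      gW_IE(P, P, fill::zeros), gW_net(K, K, fill::zeros);
  vec gb_net(K, fill::zeros), ggain_net(K, fill::zeros);
  vec gaE(P, fill::zeros), gaI(P, fill::zeros), gaA(P, fill::zeros);
  vec g_rgain(P, fill::zeros), g_roff(P, fill::zeros);
  double gbeta = 0.0;
  vec dhE(P, fill::zeros), dhI(P, fill::zeros), dhA(P, fill::zeros),
      dhnet(K, fill::zeros);
  const double scale = 2.0 / (double)(P * L);

  for (uword l = L; l-- > 0;) {
    vec dpred = scale * R.col(l);
    g_rgain += dpred % HE.col(l + 1);
    g_roff += dpred;
    dhE += readout_gain % dpred;

    // network recurrence branch
    vec hnet_new = HNET.col(l + 1);
    vec dz = dhnet % (1.0 - square(hnet_new));
    gW_net += dz * HNET.col(l).t();
    gb_net += dz;
    vec dhnet_old = W_net.t() * dz;

    // adaptation branch
    vec dhA_old = dhA % (1.0 - aA);
    gaA += dhA % (HE.col(l) - HA.col(l));
    vec dhE_old = dhA % aA;

    // inhibitory branch
    gaI += dhI % (SI.col(l) - HI.col(l));
    vec dhI_old = dhI % (1.0 - aI);
    vec duI = dhI % aI % SI.col(l) % (1.0 - SI.col(l));
    gW_EI += duI * HE.col(l).t();
    dhE_old += W_EI.t() * duI;

    // excitatory branch
    gaE += dhE % (SE.col(l) - HE.col(l));
    dhE_old += dhE % (1.0 - aE);
    vec dI = dhE % aE % SE.col(l) % (1.0 - SE.col(l));
    dhE_old += W_EE.t() * dI;
    dhI_old += W_IE.t() * dI;
    dhA_old += -beta * dI;
    gbeta += -dot(dI, HA.col(l));
    gW_EE += dI * HE.col(l).t();
    gW_IE += dI * HI.col(l).t();

    // top-down term: I_E_p includes gain[k(p)] * hnet_old[k(p)]
    vec sumdI(K, fill::zeros);
    for (uword p = 0; p < P; ++p) sumdI(net_index(p)) += dI(p);
    ggain_net += HNET.col(l) % sumdI;
    dhnet_old += gain_net % sumdI;

    dhE = dhE_old; dhI = dhI_old; dhA = dhA_old; dhnet = dhnet_old;
  }

  // chain a = dt/tau -> tau, and restrict parcel matrices to learnable entries
  vec gtau_E = gaE % (-dt / square(tau_E));
  vec gtau_I = gaI % (-dt / square(tau_I));
  vec gtau_A = gaA % (-dt / square(tau_A));
  gW_EE %= mask_EE; gW_EI %= mask_EI; gW_IE %= mask_IE;

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("W_EE") = gW_EE, Rcpp::Named("W_EI") = gW_EI,
          Rcpp::Named("W_IE") = gW_IE, Rcpp::Named("W_net") = gW_net,
          Rcpp::Named("b_net") = gb_net, Rcpp::Named("gain_net") = ggain_net,
          Rcpp::Named("tau_E") = gtau_E, Rcpp::Named("tau_I") = gtau_I,
          Rcpp::Named("tau_A") = gtau_A, Rcpp::Named("beta") = gbeta,
          Rcpp::Named("readout_gain") = g_rgain,
          Rcpp::Named("readout_offset") = g_roff),
      Rcpp::Named("h_E") = HE.col(L), Rcpp::Named("h_I") = HI.col(L),
      Rcpp::Named("h_A") = HA.col(L), Rcpp::Named("h_net") = HNET.col(L));
}

// Closed-loop simulation: the readout of h_E plus pre-drawn observation noise
// is fed back as the next input sample. noise must be P x T (column 1 seeds
// the first sample together with x1).
// [[Rcpp::export]]
Rcpp::List birnn_simulate_cpp(const arma::mat& noise, const arma::vec& x1,
                              const arma::mat& W_EE, const arma::mat& W_EI,
                              const arma::mat& W_IE, const arma::mat& W_net,
                              const arma::vec& b_net, const arma::vec& gain_net,
                              const arma::vec& tau_E, const arma::vec& tau_I,
                              const arma::vec& tau_A, double beta,
                              const arma::vec& readout_gain,
                              const arma::vec& readout_offset,
                              const arma::mat& W_in,
                              const arma::uvec& net_index, double dt,
                              const arma::vec& hE0, const arma::vec& hI0,
                              const arma::vec& hA0, const arma::vec& hnet0) {
  const uword P = noise.n_rows, T = noise.n_cols;
  vec aE = dt / tau_E, aI = dt / tau_I, aA = dt / tau_A;
  vec hE = hE0, hI = hI0, hA = hA0, hnet = hnet0;
  mat X(P, T);
  X.col(0) = x1;
  StepWork w;
  for (uword t = 0; t + 1 < T; ++t) {
    birnn_step_inner(X.col(t), hE, hI, hA, hnet, W_EE, W_EI, W_IE, W_net,
                     b_net, gain_net, aE, aI, aA, beta, W_in, net_index, w);
    hE = w.hE; hI = w.hI; hA = w.hA; hnet = w.hnet;
    X.col(t + 1) = readout_gain % hE + readout_offset + noise.col(t + 1);
    if (!X.col(t + 1).is_finite()) {
      Rcpp::stop("simulation diverged at time index %d", (int)(t + 2));
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("X") = X, Rcpp::Named("h_E") = hE, Rcpp::Named("h_I") = hI,
      Rcpp::Named("h_A") = hA, Rcpp::Named("h_net") = hnet);
}
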