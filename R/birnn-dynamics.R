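#' Hidden state of the recurrent neural-mass model
#'
#' Four biologically grounded state blocks: per-parcel excitatory (`h_E`),
#' inhibitory (`h_I`), and slow adaptation (`h_A`) population states, all in
#' `[0, 1]`, plus the network state `h_net` in `(-1, 1)` summarizing the four
#' canonical large-scale systems.
#'
#' @param h_E,h_I,h_A Numeric vectors of length `n_parcels` in `[0, 1]`.
#' @param h_net Numeric vector of length `n_networks` in `(-1, 1)`.
#' @return A `birnn_state` object.
#' @export
birnn_state <- function(h_E, h_I, h_A, h_net) {
  stopifnot(length(h_E) == length(h_I), length(h_I) == length(h_A))
  if (any(!is.finite(c(h_E, h_I, h_A, h_net)))) {
    abort("non-finite state.", class = "birnn_numeric_error")
  }
  structure(list(h_E = as.numeric(h_E), h_I = as.numeric(h_I),
                 h_A = as.numeric(h_A), h_net = as.numeric(h_net)),
            class = "birnn_state")
}

#' Default mid-range initial state
#'
#' Populations start at the middle of their admissible range (0.5) and the
#' network state at 0, so every bound-preservation guarantee applies from the
#' first step.
#'
#' @param n_parcels,n_networks Dimensions.
#' @return A [birnn_state()].
#' @export
default_state <- function(n_parcels, n_networks = 4) {
  birnn_state(rep(0.5, n_parcels), rep(0.5, n_parcels), rep(0.5, n_parcels),
              rep(0, n_networks))
}

#' Total synaptic input to the excitatory populations
#'
#' Each parcel's excitatory population receives five inputs: the observed
#' activity `x_t`, top-down drive from its network's state (uniform pattern
#' scaled by the per-network gain), recurrent excitation `W_EE h_E`, recurrent
#' inhibition `W_IE h_I` (nonpositive weights), and subtractive adaptation
#' `-beta h_A`.
#'
#' @param x_t Observed parcel activity vector at time t.
#' @param state A [birnn_state()] (the time-t state; the previous network
#'   state feeds the top-down term).
#' @param params A [birnn_params()] object.
#' @param projection A [network_projection()].
#' @return Numeric vector `I_E` of synaptic inputs, one per parcel.
#' @export
excitatory_input <- function(x_t, state, params, projection) {
  if (any(!is.finite(x_t))) {
    abort("non-finite input.", class = "birnn_numeric_error")
  }
  topdown <- (params$gain_net * state$h_net)[projection$net_index]
  as.numeric(x_t + topdown + params$W_EE %*% state$h_E +
               params$W_IE %*% state$h_I - params$beta * state$h_A)
}

#' One forward-Euler step of the coupled neural-mass dynamics
#'
#' All population updates read the time-t states (simultaneous update), and
#' the excitatory input uses the previous network state; the network state is
#' then refreshed from the current input:
#' \deqn{h_E \leftarrow h_E + (dt/\tau_E)(-h_E + \sigma(I_E))}
#' \deqn{h_I \leftarrow h_I + (dt/\tau_I)(-h_I + \sigma(W_{EI} h_E))}
#' \deqn{h_A \leftarrow h_A + (dt/\tau_A)(-h_A + h_E)}
#' \deqn{h_{net} \leftarrow \tanh(W_{in} x_t + W_{net} h_{net} + b_{net})}
#' With `dt/tau <= 1` each population update is a convex combination of the
#' current state and a value in `[0, 1]`, so states stay in `[0, 1]`.
#'
#' @inheritParams excitatory_input
#' @return The [birnn_state()] at time t+1.
#' @export
birnn_step <- function(state, x_t, params, projection) {
  aE <- params$dt / params$tau_E
  aI <- params$dt / params$tau_I
  aA <- params$dt / params$tau_A
  if (any(c(aE, aI, aA) > 1 + 1e-12)) {
    abort("unstable step: dt/tau > 1.", class = "birnn_stability_error")
  }
  I_E <- excitatory_input(x_t, state, params, projection)
  h_E <- (1 - aE) * state$h_E + aE * sigmoid(I_E)
  h_I <- (1 - aI) * state$h_I + aI * sigmoid(as.numeric(params$W_EI %*% state$h_E))
  h_A <- (1 - aA) * state$h_A + aA * state$h_E
  h_net <- tanh(as.numeric(projection$W_in %*% x_t +
                             params$W_net %*% state$h_net + params$b_net))
  birnn_state(h_E, h_I, h_A, h_net)
}

#' Roll the model forward over a recording
#'
#' Iterates [birnn_step()] over `t = 1 .. T-1`; the one-step prediction of the
#' observed signal at `t+1` is the affine readout of the excitatory state,
#' `readout_gain * h_E(t+1) + readout_offset`. Deterministic given its inputs.
#'
#' @param params A [birnn_params()] object.
#' @param series A [parcel_ts()] object (or plain parcels x samples matrix).
#' @param projection A [network_projection()].
#' @param initial_state Optional [birnn_state()]; defaults to
#'   [default_state()].
#' @param keep_states Return full state trajectories (parcels x T matrices)?
#' @param engine `"cpp"` (compiled rollout, default) or `"r"` (reference
#'   implementation composing [birnn_step()]).
#' @return List with `pred` (parcels x (T-1) predictions of samples `2..T`),
#'   `final_state`, and -- when `keep_states` -- trajectories `HE`, `HI`,
#'   `HA`, `HNET` whose column t is the state at time t (column 1 the initial
#'   state).
#' @export
birnn_forward <- function(params, series, projection, initial_state = NULL,
                          keep_states = FALSE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  X <- if (inherits(series, "parcel_ts")) series$values else as.matrix(series)
  if (ncol(X) < 2) abort("need T >= 2.", class = "birnn_shape_error")
  s0 <- initial_state %||% default_state(params$n_parcels, params$n_networks)
  if (engine == "r") {
    st <- s0
    P <- nrow(X); Tn <- ncol(X)
    pred <- matrix(NA_real_, P, Tn - 1)
    for (t in seq_len(Tn - 1)) {
      st <- birnn_step(st, X[, t], params, projection)
      pred[, t] <- params$readout_gain * st$h_E + params$readout_offset
      if (any(!is.finite(pred[, t]))) {
        abort(sprintf("divergence at time index %d.", t + 1),
              class = "birnn_divergence_error")
      }
    }
    return(list(pred = pred, final_state = st))
  }
  out <- birnn_rollout_cpp(
    X, params$W_EE, params$W_EI, params$W_IE, params$W_net, params$b_net,
    params$gain_net, params$tau_E, params$tau_I, params$tau_A, params$beta,
    params$readout_gain, params$readout_offset, projection$W_in,
    projection$net_index - 1L, params$dt, s0$h_E, s0$h_I, s0$h_A, s0$h_net,
    keep_states)
  res <- list(pred = out$pred,
              final_state = birnn_state(out$h_E, out$h_I, out$h_A, out$h_net))
  if (keep_states) res[c("HE", "HI", "HA", "HNET")] <-
      out[c("HE", "HI", "HA", "HNET")]
  res
}
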