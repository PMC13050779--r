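#' Parameter set of the biologically informed recurrent neural-mass model
#'
#' Bundles every learnable and fixed quantity of the model. Parcel-level
#' coupling obeys Dale's law: `W_EE` (excitatory-to-excitatory) and `W_EI`
#' (excitatory-to-inhibitory) are elementwise nonnegative, `W_IE`
#' (inhibitory-to-excitatory) nonpositive. Binary sparsity `masks` pin
#' masked-out entries at exactly zero. Population time constants are
#' per-parcel vectors in milliseconds, bounded to physiological ranges
#' (excitatory 5-30 ms, inhibitory 10-100 ms, adaptation 50-500 ms by
#' default). `W_net` is the signed, directed network-to-network coupling --
#' entry (i, j) is the influence of network j on network i -- and is the
#' model's central interpretable output.
#'
#' @param W_EE,W_EI,W_IE Parcel coupling matrices (parcels x parcels).
#' @param W_net Network coupling matrix (networks x networks).
#' @param b_net Network bias vector.
#' @param gain_net Nonnegative per-network gain scaling the uniform top-down
#'   feedback pattern.
#' @param tau_E,tau_I,tau_A Per-parcel time constants, ms.
#' @param beta Nonnegative scalar adaptation strength.
#' @param masks List with binary matrices `EE`, `EI`, `IE`.
#' @param readout_gain,readout_offset Per-parcel affine readout mapping the
#'   excitatory state to observation units.
#' @param dt Integration step in ms (fixed; must satisfy `dt <= min(tau)`).
#' @param tau_bounds List of `c(low, high)` ranges for `E`, `I`, `A`.
#' @param network_names,parcel_ids Optional dimension labels.
#' @return A validated `birnn_params` object.
#' @export
birnn_params <- function(W_EE, W_EI, W_IE, W_net, b_net, gain_net,
                         tau_E, tau_I, tau_A, beta, masks,
                         readout_gain = rep(1, nrow(W_EE)),
                         readout_offset = rep(0, nrow(W_EE)),
                         dt = 1,
                         tau_bounds = list(E = c(5, 30), I = c(10, 100),
                                           A = c(50, 500)),
                         network_names = NULL, parcel_ids = NULL) {
  p <- structure(
    list(W_EE = as.matrix(W_EE), W_EI = as.matrix(W_EI),
         W_IE = as.matrix(W_IE), W_net = as.matrix(W_net),
         b_net = as.numeric(b_net), gain_net = as.numeric(gain_net),
         tau_E = as.numeric(tau_E), tau_I = as.numeric(tau_I),
         tau_A = as.numeric(tau_A), beta = as.numeric(beta), masks = masks,
         readout_gain = as.numeric(readout_gain),
         readout_offset = as.numeric(readout_offset), dt = dt,
         tau_bounds = tau_bounds,
         n_parcels = nrow(as.matrix(W_EE)), n_networks = nrow(as.matrix(W_net)),
         network_names = network_names, parcel_ids = parcel_ids),
    class = "birnn_params")
  issues <- validate_birnn_params(p)
  if (length(issues) > 0) {
    abort(paste0("invalid parameters: ", paste(issues, collapse = "; ")),
          class = "birnn_param_error")
  }
  p
}

#' Check all structural invariants of a parameter set
#'
#' @param params A `birnn_params` object.
#' @return Character vector of violated invariants (empty when valid).
#' @export
validate_birnn_params <- function(params) {
  issues <- character()
  note <- function(cond, msg) if (cond) issues <<- c(issues, msg)
  P <- params$n_parcels
  note(!all(vapply(list(params$W_EE, params$W_EI, params$W_IE),
                   function(m) all(dim(m) == c(P, P)), TRUE)),
       "parcel matrices must be square and consistent")
  note(dale_violations(params) > 0, "Dale's law violated")
  note(any(params$W_EE[params$masks$EE == 0] != 0) ||
         any(params$W_EI[params$masks$EI == 0] != 0) ||
         any(params$W_IE[params$masks$IE == 0] != 0),
       "masked-out entries must be exactly zero")
  note(tau_violations(params) > 0, "time constants out of range")
  note(params$dt <= 0 || params$dt / min(params$tau_E, params$tau_I,
                                         params$tau_A) > 1,
       "dt/min(tau) must be <= 1")
  note(params$beta < 0, "beta must be nonnegative")
  note(any(params$gain_net < 0), "gain_net must be nonnegative")
  note(!all(is.finite(unlist(params[c("W_EE", "W_EI", "W_IE", "W_net",
                                      "b_net", "tau_E", "tau_I", "tau_A")]))),
       "non-finite parameter values")
  issues
}

#' Count Dale's-law sign violations
#'
#' @param params A `birnn_params` object.
#' @return Number of entries with the biologically wrong sign (negative in
#'   `W_EE`/`W_EI`, positive in `W_IE`).
#' @export
dale_violations <- function(params) {
  sum(params$W_EE < 0) + sum(params$W_EI < 0) + sum(params$W_IE > 0)
}

#' Count time constants outside their physiological ranges
#'
#' @param params A `birnn_params` object.
#' @param bounds Ranges as in [birnn_params()]; defaults to the ones stored in
#'   `params`.
#' @return Number of out-of-range time constants.
#' @export
tau_violations <- function(params, bounds = params$tau_bounds) {
  out <- function(tau, b) sum(tau < b[1] - 1e-12 | tau > b[2] + 1e-12)
  out(params$tau_E, bounds$E) + out(params$tau_I, bounds$I) +
    out(params$tau_A, bounds$A)
}

#' Binary sparsity mask with fixed connection budget
#'
#' Returns an `n x n` 0/1 matrix with exactly `round(density * n^2)` ones.
#' Diagonal entries (local recurrence) are retained first, within the budget;
#' remaining connections are drawn at random. When parcel `distances` are
#' supplied, off-diagonal retention probability decays exponentially with
#' distance, favouring short-range wiring the way cortical connectivity does.
#'
#' @param n Matrix dimension.
#' @param density Fraction of retained connections in (0, 1].
#' @param distances Optional symmetric `n x n` distance matrix.
#' @param seed Integer seed; the mask is a pure function of its arguments.
#' @return Binary matrix with the exact connection count.
#' @export
make_sparsity_mask <- function(n, density, distances = NULL, seed = 1) {
  if (!is.numeric(density) || density <= 0 || density > 1) {
    abort("`density` must be in (0, 1].", class = "birnn_config_error")
  }
  budget <- round(density * n^2)
  mask <- matrix(0, n, n)
  n_diag <- min(n, budget)
  if (n_diag > 0) diag(mask)[seq_len(n_diag)] <- 1
  remaining <- budget - n_diag
  if (remaining > 0) {
    off <- which(row(mask) != col(mask))
    wts <- if (is.null(distances)) {
      rep(1, length(off))
    } else {
      d <- as.matrix(distances)[off]
      exp(-d / mean(d))
    }
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, "mask", n, round(density * 1e6)))
    keep <- sample(off, remaining, prob = wts)
    mask[keep] <- 1
  }
  mask
}

# save/restore .Random.seed so mask generation never perturbs caller RNG state
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Initialize a Dale-compliant parameter set
#'
#' Draws small nonnegative excitatory couplings, nonpositive
#' inhibitory-to-excitatory couplings, per-parcel time constants inside their
#' physiological ranges with inhibitory kinetics initialized slower than
#' excitatory, and a weak random network coupling. Deterministic given `seed`.
#'
#' @param n_parcels,n_networks Dimensions.
#' @param projection Optional [network_projection()] supplying labels.
#' @param config Named list of initialization settings: `density` (0.3),
#'   `w_scale` (0.1, uniform upper bound for parcel couplings), `wnet_sd`
#'   (0.1), `beta` (0.1), `dt` (1 ms), `tau_bounds`, `distances` (optional
#'   parcel distance matrix for the mask).
#' @param seed Integer seed.
#' @return A `birnn_params` object passing every invariant.
#' @export
init_birnn_params <- function(n_parcels, n_networks = 4, projection = NULL,
                              config = list(), seed = 1) {
  cfg <- utils::modifyList(
    list(density = 0.3, w_scale = 0.1, wnet_sd = 0.1, beta = 0.1, dt = 1,
         tau_bounds = list(E = c(5, 30), I = c(10, 100), A = c(50, 500)),
         distances = NULL),
    config)
  if (!is.numeric(cfg$density) || cfg$density <= 0 || cfg$density > 1) {
    abort("`density` must be in (0, 1].", class = "birnn_config_error")
  }
  if (any(vapply(cfg$tau_bounds, function(b) b[1] >= b[2], TRUE))) {
    abort("tau bounds must satisfy low < high.", class = "birnn_config_error")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "init", n_parcels, n_networks))
  P <- n_parcels; K <- n_networks
  masks <- list(
    EE = make_sparsity_mask(P, cfg$density, cfg$distances, derive_seed(seed, "EE")),
    EI = make_sparsity_mask(P, cfg$density, cfg$distances, derive_seed(seed, "EI")),
    IE = make_sparsity_mask(P, cfg$density, cfg$distances, derive_seed(seed, "IE")))
  draw <- function() matrix(runif(P * P, 0, cfg$w_scale), P, P)
  birnn_params(
    W_EE = draw() * masks$EE, W_EI = draw() * masks$EI,
    W_IE = -draw() * masks$IE,
    W_net = matrix(rnorm(K * K, 0, cfg$wnet_sd), K, K),
    b_net = rep(0, K), gain_net = rep(1, K),
    tau_E = runif(P, 10, 20), tau_I = runif(P, 30, 60),
    tau_A = runif(P, 100, 300), beta = cfg$beta, masks = masks,
    dt = cfg$dt, tau_bounds = cfg$tau_bounds,
    network_names = if (!is.null(projection)) projection$network_names,
    parcel_ids = if (!is.null(projection)) projection$parcel_ids)
}

#' Project couplings onto the Dale-compliant set
#'
#' Clamps biologically wrong-signed entries to zero (negative excitatory,
#' positive inhibitory-to-excitatory couplings) and re-zeroes masked-out
#' entries. Idempotent; all other fields are untouched.
#'
#' @param params A `birnn_params` object (possibly violating constraints
#'   mid-optimization).
#' @return Dale-compliant `birnn_params`.
#' @export
apply_dales_law <- function(params) {
  params$W_EE <- pmax(params$W_EE, 0) * params$masks$EE
  params$W_EI <- pmax(params$W_EI, 0) * params$masks$EI
  params$W_IE <- pmin(params$W_IE, 0) * params$masks$IE
  params
}

#' Clip time constants into physiological ranges
#'
#' @param params A `birnn_params` object.
#' @param bounds List of `c(low, high)` per population (`E`, `I`, `A`);
#'   defaults to the ranges stored in `params`.
#' @return `birnn_params` with each tau clipped into its range.
#' @export
clamp_time_constants <- function(params, bounds = params$tau_bounds) {
  if (any(vapply(bounds, function(b) b[1] >= b[2], TRUE))) {
    abort("tau bounds must satisfy low < high.", class = "birnn_config_error")
  }
  clip <- function(tau, b) pmin(pmax(tau, b[1]), b[2])
  params$tau_E <- clip(params$tau_E, bounds$E)
  params$tau_I <- clip(params$tau_I, bounds$I)
  params$tau_A <- clip(params$tau_A, bounds$A)
  params
}

#' @export
print.birnn_params <- function(x, ...) {
  cat(sprintf(
    "<birnn_params> %d parcels, %d networks | density %.2f | dt %g ms | beta %.3g\n",
    x$n_parcels, x$n_networks, mean(x$masks$EE), x$dt, x$beta))
  invisible(x)
}

#' Serialize a parameter checkpoint to JSON
#'
#' @param params A `birnn_params` object.
#' @param path Destination `.json` file.
#' @return `path`, invisibly.
#' @export
write_birnn_params <- function(params, path) {
  payload <- unclass(params)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a parameter checkpoint written by [write_birnn_params()]
#'
#' @param path A `.json` checkpoint.
#' @return A `birnn_params` object.
#' @export
read_birnn_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- birnn_params(
    W_EE = x$W_EE, W_EI = x$W_EI, W_IE = x$W_IE, W_net = x$W_net,
    b_net = x$b_net, gain_net = x$gain_net, tau_E = x$tau_E, tau_I = x$tau_I,
    tau_A = x$tau_A, beta = x$beta,
    masks = lapply(x$masks, as.matrix),
    readout_gain = x$readout_gain, readout_offset = x$readout_offset,
    dt = x$dt, tau_bounds = lapply(x$tau_bounds, as.numeric),
    network_names = x$network_names, parcel_ids = x$parcel_ids)
  if (!is.null(x$signal_sd)) p$signal_sd <- x$signal_sd
  p
}
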