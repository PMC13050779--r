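#' Built-in network-coupling templates
#'
#' Ground-truth 4x4 signed coupling templates (entry (i, j) = influence of
#' network j on network i; order DMN, TPN, SN, Other) used by the synthetic
#' cohort generator:
#'
#' * `"task"` / `"rest"` mirror the qualitative pattern this model family
#'   reports on real encoding-task EEG -- salience-driven facilitation of both
#'   DMN and TPN, task-positive inhibition of DMN that strengthens at rest,
#'   self-inhibition within DMN and TPN, and a sign flip of the DMN-to-SN
#'   influence between task (weakly positive) and rest (strongly negative).
#'   Magnitudes are template choices on the order of reported group means
#'   (about +1.4 facilitation, -1.8 inhibition), not reproduction targets.
#' * `"strong"` plants 6 strong cells (|w| >= 1, mixed signs) and zeros
#'   elsewhere -- the parameter-recovery benchmark.
#' * `"ambiguity"` plants a single strongly negative task-positive-to-default
#'   influence fed by a slow task-positive self-loop -- the fixture for
#'   contrasting signed model-based couplings with unsigned Granger F
#'   statistics.
#' * `"null"` is all zeros.
#'
#' @param name Template name.
#' @return A 4x4 numeric matrix with network dimnames.
#' @export
wnet_template <- function(name = c("task", "rest", "strong", "ambiguity",
                                   "null")) {
  name <- match.arg(name)
  nm <- c("DMN", "TPN", "SN", "Other")
  w <- matrix(0, 4, 4, dimnames = list(target = nm, source = nm))
  set_ <- function(target, source, value) w[target, source] <<- value
  if (name == "task") {
    set_("DMN", "DMN", -0.67); set_("TPN", "TPN", -0.67)
    set_("DMN", "TPN", -1.17)                  # TPN -> DMN inhibition
    set_("DMN", "SN", 0.85); set_("TPN", "SN", 1.41)  # SN facilitation
    set_("SN", "SN", 0.36)
    set_("SN", "DMN", 0.12)                    # DMN -> SN weakly positive
  } else if (name == "rest") {
    set_("DMN", "DMN", -0.47); set_("TPN", "TPN", -0.70)
    set_("DMN", "TPN", -1.81)                  # stronger inhibition at rest
    set_("DMN", "SN", 0.37); set_("TPN", "SN", 1.47)
    set_("SN", "DMN", -0.51)                   # DMN -> SN sign flip
  } else if (name == "strong") {
    # marginal self-loops make each network a near-critical slow integrator:
    # fluctuations are large and slow enough to survive the excitatory
    # populations' low-pass filtering without the bistable trapping of
    # supercritical loops or the sample-rate oscillation of rotational
    # cross-coupling; mixed-sign cross couplings shape the joint dynamics
    diag(w) <- 1.0                                     # four slow self-loops
    set_("DMN", "TPN", -1.0)                           # TPN inhibits DMN
    set_("Other", "SN", -1.1)                          # SN suppresses Other
  }
  w
}

#' Specification of a synthetic cohort
#'
#' Describes the cohort the generator emulates: 15 subjects with 46 cortical
#' parcels in 4 networks by default, one recording per condition, each
#' simulated from the model's own forward dynamics under known sparse
#' Dale-compliant parcel connectivity, a condition-specific network-coupling
#' template with per-subject jitter, and additive white observation noise on
#' the (approximately standardized) observation scale.
#'
#' @param n_subjects,n_parcels,n_networks Cohort dimensions.
#' @param T_samples Samples per condition (at the nominal 1000 Hz).
#' @param conditions Named list of 4x4 coupling templates, one per condition
#'   (condition names must be valid [parcel_ts()] conditions).
#' @param subject_variability_sd SD of per-subject Gaussian jitter added to
#'   every template cell.
#' @param noise_sd Observation-noise SD.
#' @param density Sparsity of the parcel coupling matrices.
#' @param seed Integer seed; every generated object is a pure function of
#'   (seed, subject, condition).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 15, n_parcels = 46, n_networks = 4,
                        T_samples = 10000,
                        conditions = list(task = wnet_template("task"),
                                          rest = wnet_template("rest")),
                        subject_variability_sd = 0.2, noise_sd = 0.2,
                        density = 0.3, seed = 1) {
  stopifnot(n_subjects >= 1, n_parcels >= n_networks, T_samples >= 2,
            noise_sd >= 0, subject_variability_sd >= 0,
            length(conditions) >= 1, !is.null(names(conditions)))
  structure(list(n_subjects = n_subjects, n_parcels = n_parcels,
                 n_networks = n_networks, T_samples = T_samples,
                 conditions = conditions,
                 subject_variability_sd = subject_variability_sd,
                 noise_sd = noise_sd, density = density,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Projection implied by a cohort spec
#'
#' The packaged 46-parcel membership for the default size, a round-robin
#' synthetic membership otherwise.
#'
#' @param spec A [cohort_spec()].
#' @return A [network_projection()].
#' @export
spec_projection <- function(spec) {
  if (spec$n_parcels == 46 && spec$n_networks == 4) default_projection()
  else synthetic_membership(spec$n_parcels,
                            c("DMN", "TPN", "SN", "Other")[seq_len(spec$n_networks)])
}

#' Ground-truth parameters for one simulated subject and condition
#'
#' Draws Dale-compliant sparse parcel couplings (density from the spec,
#' diagonal retained, distance-dependent retention using parcel coordinates
#' placed on a unit sphere), time constants inside the physiological ranges
#' with inhibitory kinetics slower than excitatory, and the condition's
#' network-coupling template plus per-subject jitter. The observation readout
#' and network bias are then calibrated by damped pilot rollouts: the readout
#' offset centers each parcel's observation and `b_net` cancels the mean
#' network input, keeping the closed loop at a centered, responsive operating
#' point; the measured per-parcel signal SD makes `noise_sd` act as a
#' noise-to-signal ratio.
#'
#' @param spec A [cohort_spec()].
#' @param condition Name of a condition in `spec$conditions`.
#' @param subject Subject index (`0` gives the unjittered template).
#' @param projection Optional [network_projection()] (defaults to
#'   [spec_projection()]).
#' @return A [birnn_params()] object passing every invariant.
#' @export
generate_ground_truth <- function(spec, condition = names(spec$conditions)[1],
                                  subject = 1, projection = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), condition %in% names(spec$conditions))
  projection <- projection %||% spec_projection(spec)
  P <- spec$n_parcels; K <- spec$n_networks
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(spec$seed, "truth", subject, condition))

  # parcel coordinates on the unit sphere drive the distance prior
  coords <- matrix(rnorm(P * 3), P, 3)
  coords <- coords / sqrt(rowSums(coords^2))
  distances <- as.matrix(stats::dist(coords))
  mseed <- derive_seed(spec$seed, "mask", subject, condition)
  # ground-truth parcel coupling is confined within networks: in this model
  # family cross-network interaction is carried by the network-level coupling,
  # so the generator routes it exclusively through W_net (dense cross-network
  # parcel wiring would synchronize all parcels into one global mode that
  # swamps the network coupling's footprint)
  block <- outer(projection$net_index, projection$net_index, "==") * 1
  masks <- list(
    EE = make_sparsity_mask(P, spec$density, distances, mseed) * block,
    EI = make_sparsity_mask(P, spec$density, distances, mseed + 1L) * block,
    IE = make_sparsity_mask(P, spec$density, distances, mseed + 2L) * block)

  template <- spec$conditions[[condition]]
  jitter <- if (subject > 0 && spec$subject_variability_sd > 0) {
    matrix(rnorm(K * K, 0, spec$subject_variability_sd), K, K)
  } else matrix(0, K, K)

  # The coupling magnitudes put the ground truth in the excitation-inhibition
  # limit-cycle regime neural-mass models are built around: strong recurrent
  # excitation balanced by slightly stronger delayed inhibition, with slow
  # subtractive adaptation as a stabilizing envelope. This produces rich,
  # self-sustained broadband fluctuations -- rather than relaxation to a
  # fixed point -- so the observed series actually carries the temporal
  # dependence structure (including the network coupling's footprint) that
  # the inference stages are supposed to recover.
  draw <- function(hi) matrix(runif(P * P, 0, hi), P, P)
  params <- birnn_params(
    W_EE = draw(1.0) * masks$EE, W_EI = draw(1.0) * masks$EI,
    W_IE = -draw(1.2) * masks$IE,
    W_net = unname(as.matrix(template)[seq_len(K), seq_len(K)]) + jitter,
    b_net = rep(0, K), gain_net = rep(1, K),
    tau_E = runif(P, 5, 15), tau_I = runif(P, 20, 50),
    tau_A = runif(P, 100, 300), beta = 1.5, masks = masks,
    readout_gain = rep(3, P), readout_offset = rep(0, P),
    network_names = projection$network_names,
    parcel_ids = projection$parcel_ids)

  calibrate_readout(params, projection, spec$noise_sd,
                    seed = derive_seed(spec$seed, "cal", subject, condition))
}

# Pilot rollouts center the readout so the closed-loop input stays near the
# sigmoid populations' sensitive range, and measure the per-parcel SD of the
# noiseless readout so observation noise can be specified relative to signal.
# Rescaling the loop to unit observation variance is not an option: the
# feedback gain that would require makes the mean dynamics unstable and
# saturates the network state, destroying the coupling's footprint in the
# data. Centering is iterated because changing the offset shifts the
# operating point.
calibrate_readout <- function(params, projection, noise_sd, seed,
                              T_pilot = 2000, iterations = 12) {
  signal_sd <- rep(1, params$n_parcels)
  rho <- 0.6 # damping: full-step updates overshoot through the feedback loop
  for (it in seq_len(iterations)) {
    sim <- simulate_timeseries(params, projection, T_pilot,
                               noise_sd = noise_sd, seed = seed,
                               .return_noise = TRUE)
    r <- sim$series$values - sim$noise        # noiseless readout g*hE + c
    params$readout_offset <- params$readout_offset - rho * rowMeans(r)
    # also cancel the mean network input so the zero network state is the
    # operating point: a DC-offset tanh argument pins the network state at a
    # saturated attractor where the coupling has no dynamic footprint
    target_b <- as.numeric(-projection$W_in %*% rowMeans(sim$series$values))
    params$b_net <- (1 - rho) * params$b_net + rho * target_b
    signal_sd <- pmax(apply(r, 1, sd), 1e-6)
  }
  params$signal_sd <- signal_sd
  params
}

#' Simulate a parcel recording from known parameters
#'
#' Rolls the neural-mass dynamics forward in closed loop: the affine readout
#' of the excitatory state plus white Gaussian observation noise is fed back
#' as the next input sample, so the simulated data carries the temporal
#' dependence the model assumes. States stay bounded; the output is
#' deterministic given the seed.
#'
#' @param params Ground-truth [birnn_params()].
#' @param projection Matching [network_projection()].
#' @param T_samples Number of samples.
#' @param noise_sd Observation-noise SD, expressed relative to the per-parcel
#'   SD of the noiseless signal when the parameters carry a calibrated
#'   `signal_sd` (so it reads as a noise-to-signal ratio, equivalently the
#'   noise SD on the standardized observation scale); absolute otherwise.
#' @param seed Integer seed.
#' @param subject_id,condition Metadata for the returned series.
#' @param .return_noise Also return the noise matrix (internal calibration
#'   use).
#' @return A [parcel_ts()] object (or a list with `series` and `noise`).
#' @export
simulate_timeseries <- function(params, projection, T_samples, noise_sd = 0.2,
                                seed = 1, subject_id = "sim", condition = "rest",
                                .return_noise = FALSE) {
  stopifnot(T_samples >= 2)
  P <- params$n_parcels
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "sim"))
  sd_scale <- params$signal_sd %||% rep(1, P)
  noise <- matrix(rnorm(P * T_samples, 0, noise_sd), P, T_samples) * sd_scale
  s0 <- default_state(P, params$n_networks)
  x1 <- params$readout_gain * s0$h_E + params$readout_offset + noise[, 1]
  out <- birnn_simulate_cpp(
    noise, x1, params$W_EE, params$W_EI, params$W_IE, params$W_net,
    params$b_net, params$gain_net, params$tau_E, params$tau_I, params$tau_A,
    params$beta, params$readout_gain, params$readout_offset, projection$W_in,
    projection$net_index - 1L, params$dt, s0$h_E, s0$h_I, s0$h_A, s0$h_net)
  series <- parcel_ts(out$X, parcel_ids = projection$parcel_ids,
                      subject_id = subject_id, condition = condition)
  if (.return_noise) list(series = series, noise = noise) else series
}

#' Generate a full synthetic cohort with its ground-truth registry
#'
#' One recording per subject per condition, each simulated from that
#' subject's own jittered ground-truth parameters, which are retained for
#' recovery scoring. Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `data` (tibble: `subject_id`, `condition`, `series`
#'   list-column), `truth` (tibble: `subject_id`, `condition`, `params` and
#'   `W_net` list-columns), and the `projection`.
#' @export
generate_cohort <- function(spec) {
  projection <- spec_projection(spec)
  grid <- tidyr::expand_grid(subject = seq_len(spec$n_subjects),
                             condition = names(spec$conditions))
  rows <- purrr::pmap(grid, function(subject, condition) {
    sid <- sprintf("s%02d", subject)
    truth <- generate_ground_truth(spec, condition, subject, projection)
    series <- simulate_timeseries(
      truth, projection, spec$T_samples, noise_sd = spec$noise_sd,
      seed = derive_seed(spec$seed, "series", subject, condition),
      subject_id = sid, condition = condition)
    list(data = tibble::tibble(subject_id = sid, condition = condition,
                               series = list(series)),
         truth = tibble::tibble(subject_id = sid, condition = condition,
                                params = list(truth),
                                W_net = list(truth$W_net)))
  })
  list(data = purrr::map_dfr(rows, "data"),
       truth = purrr::map_dfr(rows, "truth"),
       projection = projection)
}

#' Generate an imagery-vividness covariate with a planted association
#'
#' Builds integer questionnaire totals (16 items on a 1-5 scale, hence the
#' 16-80 range) whose population correlation with the supplied per-subject
#' coupling values is `target_r`: the standardized couplings are mixed with
#' independent Gaussian noise in the exact proportion, rescaled to a typical
#' population distribution (mean 55.5, SD 11), then rounded and clipped into
#' range. Discretization attenuates the empirical correlation slightly.
#'
#' @param couplings Per-subject coupling values (non-constant).
#' @param target_r Desired correlation, `|target_r| < 1`.
#' @param score_range Admissible score range.
#' @param seed Integer seed.
#' @return Integer scores, one per subject.
#' @export
generate_vviq_covariate <- function(couplings, target_r, score_range = c(16, 80),
                                    seed = 1) {
  stopifnot(abs(target_r) < 1)
  if (sd(couplings) == 0) {
    abort("degenerate coupling variance.", class = "birnn_degenerate_error")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "vviq"))
  z <- as.numeric(scale(couplings))
  latent <- target_r * z + sqrt(1 - target_r^2) * rnorm(length(z))
  as.integer(pmin(pmax(round(55.5 + 11 * latent), score_range[1]),
                  score_range[2]))
}

#' Simulate a unidirectionally coupled pair of series
#'
#' `x` is white noise; `y` follows `y_t = ar * y_{t-1} + coupling * x_{t-lag}
#' + e_t`. The canonical oracle input for the Granger baseline: all temporal
#' dependence runs from x to y.
#'
#' @param coupling Coupling strength (its sign does not affect Granger F
#'   statistics -- that unsigned-ness is the point of the baseline contrast).
#' @param lag Transmission delay in samples.
#' @param T_samples Series length.
#' @param ar Autoregressive coefficient of y; needs `|ar| < 1` for
#'   stationarity.
#' @param noise_sd Innovation SD for both series.
#' @param seed Integer seed.
#' @return Tibble with columns `x` and `y`.
#' @export
simulate_var_pair <- function(coupling, lag = 1, T_samples = 2000, ar = 0.5,
                              noise_sd = 1, seed = 1) {
  if (abs(ar) >= 1) {
    abort("|ar| must be < 1 for stationarity.",
          class = "birnn_stationarity_error")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "varpair"))
  x <- rnorm(T_samples, 0, noise_sd)
  drive <- c(rep(0, lag), coupling * x[seq_len(T_samples - lag)]) +
    rnorm(T_samples, 0, noise_sd)
  y <- as.numeric(stats::filter(drive, ar, method = "recursive"))
  tibble::tibble(x = x, y = y)
}
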