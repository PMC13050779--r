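# shared fixtures: everything is generated in code at test time

tiny_projection <- function(P = 6, K = 2) {
  synthetic_membership(P, c("DMN", "TPN", "SN", "Other")[seq_len(K)])
}

tiny_params <- function(P = 6, K = 2, seed = 1, density = 1) {
  init_birnn_params(P, K, tiny_projection(P, K),
                    config = list(density = density), seed = seed)
}

# parameters with every coupling zeroed (useful for closed-form checks)
zero_params <- function(P = 6, K = 2, beta = 0) {
  p <- tiny_params(P, K)
  p$W_EE[] <- 0; p$W_EI[] <- 0; p$W_IE[] <- 0
  p$W_net[] <- 0; p$b_net[] <- 0; p$gain_net[] <- 0
  p$beta <- beta
  p
}

small_spec <- function(n_subjects = 2, n_parcels = 12, T_samples = 1200,
                       conditions = list(task = wnet_template("strong")),
                       seed = 3, ...) {
  cohort_spec(n_subjects = n_subjects, n_parcels = n_parcels,
              T_samples = T_samples, conditions = conditions, seed = seed, ...)
}

small_series <- function(T_samples = 1200, n_parcels = 12, seed = 3,
                         noise_sd = 0.2) {
  spec <- small_spec(n_parcels = n_parcels, T_samples = T_samples,
                     seed = seed, noise_sd = noise_sd)
  proj <- spec_projection(spec)
  truth <- generate_ground_truth(spec, "task", 1, proj)
  list(series = simulate_timeseries(truth, proj, T_samples, noise_sd,
                                    seed = seed + 1, condition = "task"),
       truth = truth, projection = proj, spec = spec)
}

# independent brute-force step-up FDR oracle (direct enumeration of the
# min-over-j definition; deliberately naive)
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    candidates <- sapply(k:m, function(j) m * p[ord[j]] / j)
    adj[ord[k]] <- min(1, min(candidates))
  }
  adj
}

# build a cohort of connectivity matrices from an n_subjects x 16 value matrix
matrices_from_values <- function(values, condition = "task") {
  lapply(seq_len(nrow(values)), function(i)
    connectivity_matrix(matrix(values[i, ], 4, 4),
                        subject_id = sprintf("s%02d", i),
                        condition = condition))
}
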