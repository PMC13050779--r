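#' Training configuration
#'
#' Defaults follow the published recipe for this model family: AdamW at
#' learning rate 5e-4 with weight decay 1e-5, up to 150 epochs,
#' reduce-on-plateau scheduling (patience 15 epochs, factor 0.8), early
#' stopping with patience 20 epochs restoring the best validation checkpoint,
#' and L1 regularization on all connectivity matrices with `l1_lambda = 0.001`.
#' The final `validation_fraction` of each series is held out chronologically,
#' avoiding leakage through temporal autocorrelation. Gradients are truncated
#' to windows of `window` samples with carried-over state.
#'
#' @param learning_rate,weight_decay AdamW settings.
#' @param max_epochs Maximum number of passes over the training segment.
#' @param scheduler_patience,scheduler_factor Reduce-on-plateau settings.
#' @param early_stop_patience Epochs without validation improvement tolerated
#'   before stopping.
#' @param l1_lambda Weight of the sparsity-promoting L1 term inside the
#'   biological regularizer.
#' @param bio_lambda Weight multiplying the whole biological regularizer in
#'   the loss.
#' @param validation_fraction Fraction of samples (from the end) held out.
#' @param window Truncated-backpropagation window length in samples.
#' @param improvement_tol Relative validation-loss decrease counting as an
#'   improvement for both scheduler and early stopping.
#' @param seed Integer seed controlling initialization.
#' @param init Named list forwarded to [init_birnn_params()].
#' @param distances Optional parcel distance matrix weighting the L1 term
#'   (implausibly long-range couplings are penalized more).
#' @return A `birnn_training_config` list.
#' @export
training_config <- function(learning_rate = 5e-4, weight_decay = 1e-5,
                            max_epochs = 150, scheduler_patience = 15,
                            scheduler_factor = 0.8, early_stop_patience = 20,
                            l1_lambda = 0.001, bio_lambda = 1,
                            validation_fraction = 0.2, window = 200,
                            improvement_tol = 1e-4, seed = 1, init = list(),
                            distances = NULL) {
  cfg <- list(learning_rate = learning_rate, weight_decay = weight_decay,
              max_epochs = as.integer(max_epochs),
              scheduler_patience = as.integer(scheduler_patience),
              scheduler_factor = scheduler_factor,
              early_stop_patience = as.integer(early_stop_patience),
              l1_lambda = l1_lambda, bio_lambda = bio_lambda,
              validation_fraction = validation_fraction,
              window = as.integer(window), improvement_tol = improvement_tol,
              seed = as.integer(seed), init = init, distances = distances)
  with(cfg, {
    if (learning_rate <= 0 || weight_decay < 0 || l1_lambda < 0 ||
        bio_lambda < 0 || validation_fraction <= 0 ||
        validation_fraction >= 1 || window < 2 || max_epochs < 1) {
      abort("invalid training configuration.", class = "birnn_config_error")
    }
  })
  structure(cfg, class = c("birnn_training_config", "list"))
}

#' Biological regularizer
#'
#' Sum of three penalties: squared Dale's-law violations (negative excitatory
#' or positive inhibitory-to-excitatory entries), squared time-constant
#' excursions beyond the physiological ranges, and an `l1_lambda`-weighted L1
#' penalty on all connectivity matrices (optionally distance-weighted for the
#' parcel matrices so long-range couplings cost more). Zero iff the parameters
#' are fully compliant and all couplings are zero.
#'
#' @param params A [birnn_params()] object.
#' @param config A [training_config()].
#' @return Nonnegative scalar.
#' @export
bio_regularizer <- function(params, config = training_config()) {
  dale <- sum(pmin(params$W_EE, 0)^2) + sum(pmin(params$W_EI, 0)^2) +
    sum(pmax(params$W_IE, 0)^2)
  exc <- function(tau, b) sum(pmax(tau - b[2], 0)^2 + pmin(tau - b[1], 0)^2)
  tau_term <- exc(params$tau_E, params$tau_bounds$E) +
    exc(params$tau_I, params$tau_bounds$I) +
    exc(params$tau_A, params$tau_bounds$A)
  dw <- distance_weight(params, config)
  l1 <- config$l1_lambda *
    (sum(dw * abs(params$W_EE)) + sum(dw * abs(params$W_EI)) +
       sum(dw * abs(params$W_IE)) + sum(abs(params$W_net)))
  dale + tau_term + l1
}

distance_weight <- function(params, config) {
  if (is.null(config$distances)) return(1)
  d <- as.matrix(config$distances)
  1 + d / mean(d[upper.tri(d)])
}

# analytic gradient of bio_regularizer w.r.t. each learnable block
bio_regularizer_grads <- function(params, config) {
  dw <- distance_weight(params, config)
  exc_g <- function(tau, b) 2 * (pmax(tau - b[2], 0) + pmin(tau - b[1], 0))
  list(
    W_EE = (2 * pmin(params$W_EE, 0) + config$l1_lambda * dw *
              sign(params$W_EE)) * params$masks$EE,
    W_EI = (2 * pmin(params$W_EI, 0) + config$l1_lambda * dw *
              sign(params$W_EI)) * params$masks$EI,
    W_IE = (2 * pmax(params$W_IE, 0) + config$l1_lambda * dw *
              sign(params$W_IE)) * params$masks$IE,
    W_net = config$l1_lambda * sign(params$W_net),
    tau_E = exc_g(params$tau_E, params$tau_bounds$E),
    tau_I = exc_g(params$tau_I, params$tau_bounds$I),
    tau_A = exc_g(params$tau_A, params$tau_bounds$A))
}

#' Training loss
#'
#' Mean squared one-step prediction error over all parcels and time points,
#' plus `bio_lambda` times the [bio_regularizer()].
#'
#' @param predicted,observed Matrices of identical shape (parcels x samples).
#' @param params A [birnn_params()] object.
#' @param config A [training_config()].
#' @return Scalar loss.
#' @export
birnn_loss <- function(predicted, observed, params, config = training_config()) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed))) {
    abort("prediction/observation shape mismatch.", class = "birnn_shape_error")
  }
  mean((predicted - observed)^2) + config$bio_lambda * bio_regularizer(params, config)
}

learnable_names <- c("W_EE", "W_EI", "W_IE", "W_net", "b_net", "gain_net",
                     "tau_E", "tau_I", "tau_A", "beta", "readout_gain",
                     "readout_offset")

adamw_init <- function(params) {
  zeros <- lapply(params[learnable_names], function(x) x * 0)
  list(m = zeros, v = zeros, t = 0)
}

adamw_update <- function(params, grads, opt, lr, weight_decay,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in learnable_names) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mh <- opt$m[[nm]] / (1 - beta1^opt$t)
    vh <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps) -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, opt = opt)
}

project_constraints <- function(params) {
  params <- apply_dales_law(params)
  params <- clamp_time_constants(params)
  params$beta <- max(params$beta, 0)
  params$gain_net <- pmax(params$gain_net, 0)
  params
}

window_grad <- function(Z, s, e, params, projection, state) {
  birnn_window_grad_cpp(
    Z[, s:(e + 1), drop = FALSE], params$W_EE, params$W_EI, params$W_IE,
    params$W_net, params$b_net, params$gain_net, params$tau_E, params$tau_I,
    params$tau_A, params$beta, params$readout_gain, params$readout_offset,
    projection$W_in, projection$net_index - 1L, params$dt, params$masks$EE,
    params$masks$EI, params$masks$IE, state$h_E, state$h_I, state$h_A,
    state$h_net)
}

#' Fit the model to one subject and condition
#'
#' Per-parcel z-scores the series using training-split statistics, then
#' optimizes all learnable parameters by truncated backpropagation through
#' time with AdamW. After every update the parameters are projected back onto
#' the constraint set (Dale's law, time-constant ranges, sparsity masks,
#' nonnegative adaptation and feedback gains), so compliance holds exactly at
#' every epoch, not just at convergence. The learning rate is reduced on
#' validation plateaus and training stops early when validation loss stalls,
#' restoring the best checkpoint. Deterministic given the config seed.
#'
#' @param series A [parcel_ts()] object.
#' @param projection A [network_projection()] matching the series.
#' @param config A [training_config()].
#' @param init_params Optional [birnn_params()] starting point (defaults to
#'   [init_birnn_params()] under the config seed).
#' @return A `birnn_fit` object: best-checkpoint `params`, per-epoch `history`
#'   tibble (train/validation loss, learning rate, constraint-violation
#'   counts), the standardization (`center`, `scale`), and metadata.
#' @export
train_birnn <- function(series, projection, config = training_config(),
                        init_params = NULL) {
  stopifnot(inherits(series, "parcel_ts"))
  X <- series$values
  Tn <- ncol(X)
  n_train <- floor(Tn * (1 - config$validation_fraction))
  if (n_train < config$window / 2 || Tn - n_train < 2) {
    abort("series too short to split into train/validation.",
          class = "birnn_shape_error")
  }
  center <- rowMeans(X[, seq_len(n_train), drop = FALSE])
  scale_ <- apply(X[, seq_len(n_train), drop = FALSE], 1, sd)
  scale_[scale_ == 0] <- 1
  Z <- (X - center) / scale_

  params <- init_params %||% init_birnn_params(
    nrow(X), length(projection$network_names), projection,
    config = config$init, seed = config$seed)
  params <- project_constraints(params)
  opt <- adamw_init(params)
  lr <- config$learning_rate

  starts <- seq(1L, n_train - 1L, by = config$window)
  ends <- pmin(starts + config$window - 1L, n_train - 1L)

  best <- list(val = Inf, params = params, epoch = 0L)
  sched_wait <- 0L; stop_wait <- 0L
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    state <- default_state(params$n_parcels, params$n_networks)
    for (w in seq_along(starts)) {
      res <- window_grad(Z, starts[w], ends[w], params, projection, state)
      if (!is.finite(res$loss)) {
        abort(sprintf("training diverged at epoch %d.", epoch),
              class = "birnn_training_error")
      }
      g <- res$grads
      rg <- bio_regularizer_grads(params, config)
      for (nm in names(rg)) g[[nm]] <- g[[nm]] + config$bio_lambda * rg[[nm]]
      upd <- adamw_update(params, g, opt, lr, config$weight_decay)
      params <- project_constraints(upd$params)
      opt <- upd$opt
      state <- birnn_state(res$h_E, res$h_I, res$h_A, res$h_net)
    }

    roll <- birnn_forward(params, Z, projection)
    err <- (roll$pred - Z[, 2:Tn, drop = FALSE])^2
    train_mse <- mean(err[, seq_len(n_train - 1), drop = FALSE])
    val_mse <- mean(err[, n_train:(Tn - 1), drop = FALSE])
    if (!is.finite(val_mse)) {
      abort(sprintf("training diverged at epoch %d.", epoch),
            class = "birnn_training_error")
    }
    improved <- (best$val - val_mse) / max(best$val, .Machine$double.eps) >
      config$improvement_tol || !is.finite(best$val)
    if (improved) {
      best <- list(val = val_mse, params = params, epoch = epoch)
      sched_wait <- 0L; stop_wait <- 0L
    } else {
      sched_wait <- sched_wait + 1L; stop_wait <- stop_wait + 1L
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = train_mse +
        config$bio_lambda * bio_regularizer(params, config),
      train_mse = train_mse, val_loss = val_mse, lr = lr,
      dale_violations = dale_violations(params),
      tau_violations = tau_violations(params),
      improved = improved)
    if (sched_wait >= config$scheduler_patience) {
      lr <- lr * config$scheduler_factor
      sched_wait <- 0L
    }
    if (stop_wait >= config$early_stop_patience) break
  }

  structure(
    list(params = best$params, history = dplyr::bind_rows(hist),
         best_epoch = best$epoch, val_loss = best$val, config = config,
         center = center, scale = scale_, projection = projection,
         subject_id = series$subject_id, condition = series$condition),
    class = "birnn_fit")
}

#' @export
print.birnn_fit <- function(x, ...) {
  cat(sprintf(
    "<birnn_fit> subject %s, condition %s | %d epochs (best %d), val MSE %.4g\n",
    x$subject_id, x$condition, nrow(x$history), x$best_epoch, x$val_loss))
  invisible(x)
}

#' One-step predictions from a fitted model
#'
#' @param object A `birnn_fit`.
#' @param newdata A [parcel_ts()] (defaults to refusing -- supply data).
#' @param ... Unused.
#' @return Matrix of one-step predictions (original units) for samples `2..T`.
#' @export
predict.birnn_fit <- function(object, newdata, ...) {
  Z <- (newdata$values - object$center) / object$scale
  p <- birnn_forward(object$params, Z, object$projection)$pred
  p * object$scale + object$center
}

#' Tidy the learned network coupling of a fit
#'
#' @param x A `birnn_fit`.
#' @param ... Unused.
#' @return Tibble with `source`, `target`, `weight` for the 16 directed
#'   network couplings.
#' @export
tidy.birnn_fit <- function(x, ...) {
  tidy(extract_network_connectivity(x))
}

#' One-row fit summary
#'
#' @param x A `birnn_fit`.
#' @param ... Unused.
#' @return Tibble with epochs run, best epoch, losses, and constraint audit
#'   counts (both zero by construction).
#' @export
glance.birnn_fit <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, condition = x$condition,
    n_epochs = nrow(x$history), best_epoch = x$best_epoch,
    train_loss = x$history$train_loss[x$best_epoch],
    val_loss = x$val_loss,
    dale_violations = dale_violations(x$params),
    tau_violations = tau_violations(x$params))
}
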