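test_that("sparsity masks hit the exact connection budget deterministically", {
  expect_equal(sum(make_sparsity_mask(8, 1)), 64)
  m <- make_sparsity_mask(10, 0.3, seed = 5)
  expect_equal(sum(m), 30)
  expect_true(all(diag(m) == 1)) # local recurrence retained
  expect_identical(m, make_sparsity_mask(10, 0.3, seed = 5))
  expect_false(identical(m, make_sparsity_mask(10, 0.3, seed = 6)))
  expect_error(make_sparsity_mask(10, 0), class = "birnn_config_error")
  expect_error(make_sparsity_mask(10, 1.2), class = "birnn_config_error")

  # distance weighting: nearer pairs retained more often
  coords <- cbind(seq_len(20), 0, 0)
  d <- as.matrix(dist(coords))
  hits <- Reduce(`+`, lapply(1:40, function(s) make_sparsity_mask(20, 0.3, d, s)))
  near <- abs(row(d) - col(d)) == 1
  far <- abs(row(d) - col(d)) >= 15
  expect_gt(mean(hits[near]), mean(hits[far]))
})

test_that("initialization is Dale-compliant, in-range, and seed-deterministic", {
  p1 <- init_birnn_params(46, 4, default_projection(),
                          config = list(density = 0.3), seed = 9)
  p2 <- init_birnn_params(46, 4, default_projection(),
                          config = list(density = 0.3), seed = 9)
  expect_identical(p1, p2)
  expect_length(validate_birnn_params(p1), 0)
  expect_equal(dale_violations(p1), 0)
  expect_equal(tau_violations(p1), 0)
  expect_true(all(p1$tau_I > p1$tau_E)) # slower inhibitory kinetics
  expect_equal(sum(p1$masks$EE), round(0.3 * 46^2))
  expect_true(all(diag(p1$masks$EE) == 1))
  expect_error(init_birnn_params(10, 2, config = list(density = 2)),
               class = "birnn_config_error")
  expect_error(
    init_birnn_params(10, 2, config = list(tau_bounds = list(
      E = c(30, 5), I = c(10, 100), A = c(50, 500)))),
    class = "birnn_config_error")
})

test_that("excitatory input sums its five sources", {
  pr <- tiny_projection(2, 2)
  p <- zero_params(2, 2)
  s <- birnn_state(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  x <- c(0.4, -0.2)
  expect_equal(excitatory_input(x, s, p, pr), x)

  p$beta <- 1
  s2 <- birnn_state(c(0, 0), c(0, 0), x, c(0, 0))
  expect_error(excitatory_input(c(NaN, 1), s2, p, pr),
               class = "birnn_numeric_error")
  # with h_A = x and beta = 1 the adaptation term cancels the input exactly
  # (requires x in [0,1] for a valid state)
  xa <- c(0.4, 0.2)
  sa <- birnn_state(c(0, 0), c(0, 0), xa, c(0, 0))
  expect_equal(excitatory_input(xa, sa, p, pr), c(0, 0))

  # hand-computed five-term sum on a 2-parcel instance
  ph <- zero_params(2, 2)
  ph$W_EE <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  ph$W_IE <- matrix(c(-0.5, 0, -0.1, -0.2), 2, 2)
  ph$beta <- 0.25
  ph$gain_net <- c(2, 3)
  sh <- birnn_state(c(0.5, 0.6), c(0.2, 0.1), c(0.3, 0.8), c(0.4, -0.5))
  xh <- c(1, -1)
  # parcel 1 is in network 1, parcel 2 in network 2 (round-robin membership)
  expect_equal(
    excitatory_input(xh, sh, ph, pr),
    c(1 + 2 * 0.4 + (0.1 * 0.5 + 0.3 * 0.6) + (-0.5 * 0.2 - 0.1 * 0.1) - 0.25 * 0.3,
      -1 + 3 * (-0.5) + (0.2 * 0.5 + 0.4 * 0.6) + (0 - 0.2 * 0.1) - 0.25 * 0.8))
})

test_that("one Euler step matches closed forms and fixed points", {
  pr <- tiny_projection(3, 2)
  p <- zero_params(3, 2)

  # forced I_E = 0: new h_E = h_E + (dt/tau)(-h_E + 0.5) with h_E = 0
  p$tau_E[] <- 10 # dt/tau = 0.1
  s <- birnn_state(rep(0, 3), rep(0.5, 3), rep(0, 3), rep(0, 2))
  out <- birnn_step(s, rep(0, 3), p, pr)
  expect_equal(out$h_E, rep(0.05, 3))
  expect_equal(out$h_net, rep(0, 2)) # tanh(0) = 0

  # Euler fixed point under constant input
  x <- c(0.3, -0.1, 0.7)
  hE <- sigmoid(x)
  hI <- sigmoid(as.numeric(p$W_EI %*% hE))
  hnet <- tanh(as.numeric(pr$W_in %*% x))
  fx <- birnn_state(hE, hI, hE, hnet)
  out2 <- birnn_step(fx, x, p, pr)
  expect_equal(out2$h_E, fx$h_E, tolerance = 1e-12)
  expect_equal(out2$h_I, fx$h_I, tolerance = 1e-12)
  expect_equal(out2$h_A, fx$h_A, tolerance = 1e-12)
  expect_equal(out2$h_net, fx$h_net, tolerance = 1e-12)

  # dt/tau > 1 is rejected
  bad <- p; bad$tau_E[1] <- 0.5
  expect_error(birnn_step(s, rep(0, 3), bad, pr),
               class = "birnn_stability_error")
})

test_that("forward rollout composes steps, keeps bounds, and is reproducible", {
  pr <- tiny_projection(2, 2)
  p <- tiny_params(2, 2, seed = 4)
  p$W_net <- matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2)

  x2 <- matrix(rnorm(2 * 2), 2, 2)
  expect_equal(ncol(birnn_forward(p, x2, pr)$pred), 1)

  x <- matrix(rnorm(2 * 4), 2, 4)
  s <- default_state(2, 2)
  manual <- s
  pred <- matrix(0, 2, 3)
  for (t in 1:3) {
    manual <- birnn_step(manual, x[, t], p, pr)
    pred[, t] <- p$readout_gain * manual$h_E + p$readout_offset
  }
  roll <- birnn_forward(p, x, pr, engine = "r")
  expect_equal(roll$pred, pred)
  expect_equal(roll$final_state, manual)
  # compiled rollout agrees bitwise with the composed reference
  cpp <- birnn_forward(p, x, pr, engine = "cpp")
  expect_equal(cpp$pred, roll$pred, tolerance = 1e-14)
  expect_equal(cpp$final_state$h_net, roll$final_state$h_net,
               tolerance = 1e-14)
  # the compiled rollout itself is exactly reproducible
  expect_identical(cpp$pred, birnn_forward(p, x, pr, engine = "cpp")$pred)

  long <- matrix(rnorm(2 * 500, sd = 2), 2, 500)
  st <- birnn_forward(p, long, pr, keep_states = TRUE)
  for (nm in c("HE", "HI", "HA")) {
    expect_true(all(st[[nm]] >= 0 & st[[nm]] <= 1))
  }
  expect_true(all(abs(st$HNET) <= 1))

  x[1, 3] <- NaN
  expect_error(birnn_forward(p, x, pr), "time index")
})

test_that("zero network recurrence degenerates to a memoryless projection", {
  pr <- tiny_projection(4, 2)
  p <- tiny_params(4, 2, seed = 2)
  p$W_net[] <- 0; p$b_net[] <- 0
  x <- matrix(rnorm(4 * 30), 4, 30)
  st <- birnn_forward(p, x, pr, keep_states = TRUE)
  for (t in 1:29) {
    expect_equal(st$HNET[, t + 1], tanh(as.numeric(pr$W_in %*% x[, t])),
                 tolerance = 1e-12)
  }
})

test_that("with beta = 0 the adaptation state cannot influence predictions", {
  pr <- tiny_projection(3, 2)
  p <- tiny_params(3, 2, seed = 6)
  p$beta <- 0
  x <- matrix(rnorm(3 * 50), 3, 50)
  s_lo <- birnn_state(rep(0.5, 3), rep(0.5, 3), rep(0, 3), rep(0, 2))
  s_hi <- birnn_state(rep(0.5, 3), rep(0.5, 3), rep(1, 3), rep(0, 2))
  expect_equal(birnn_forward(p, x, pr, s_lo)$pred,
               birnn_forward(p, x, pr, s_hi)$pred)
})

test_that("Dale projection clamps, respects masks, and is idempotent", {
  p <- tiny_params(4, 2, seed = 8)
  raw <- p
  raw$W_EE[1, 2] <- -0.5
  raw$W_IE[2, 1] <- 0.3
  fixed <- apply_dales_law(raw)
  expect_equal(fixed$W_EE[1, 2], 0)
  expect_equal(fixed$W_IE[2, 1], 0)
  expect_equal(dale_violations(fixed), 0)
  expect_identical(apply_dales_law(fixed), fixed) # idempotent
  expect_identical(apply_dales_law(p), p)         # compliant unchanged

  masked <- p
  masked$masks$EE[1, 3] <- 0
  masked$W_EE[1, 3] <- 0.7
  expect_equal(apply_dales_law(masked)$W_EE[1, 3], 0)
})

test_that("time constants clip into their physiological ranges", {
  p <- tiny_params(3, 2)
  p$tau_E <- c(2, 50, 100) # below, in-range-for-I, above
  p$tau_I <- c(50, 5, 200)
  out <- clamp_time_constants(p)
  expect_equal(out$tau_E, c(5, 30, 30))
  expect_equal(out$tau_I, c(50, 10, 100))
  expect_error(clamp_time_constants(p, list(E = c(30, 5), I = c(10, 100),
                                            A = c(50, 500))),
               class = "birnn_config_error")
})

test_that("analytic BPTT gradients match central finite differences", {
  set.seed(42)
  P <- 4; K <- 2; L <- 6
  pr <- tiny_projection(P, K)
  p <- tiny_params(P, K, seed = 3, density = 0.8)
  p$b_net <- rnorm(K, 0, 0.1)
  p$W_net <- matrix(rnorm(K * K, 0, 0.5), K, K)
  p$beta <- 0.3
  Z <- matrix(rnorm(P * (L + 1)), P, L + 1)
  s0 <- default_state(P, K)
  wg <- function(pp) {
    birnn:::birnn_window_grad_cpp(
      Z, pp$W_EE, pp$W_EI, pp$W_IE, pp$W_net, pp$b_net, pp$gain_net,
      pp$tau_E, pp$tau_I, pp$tau_A, pp$beta, pp$readout_gain,
      pp$readout_offset, pr$W_in, pr$net_index - 1L, pp$dt, pp$masks$EE,
      pp$masks$EI, pp$masks$IE, s0$h_E, s0$h_I, s0$h_A, s0$h_net)
  }
  res <- wg(p)
  eps <- 1e-6
  for (nm in c("W_EE", "W_IE", "W_net", "b_net", "gain_net", "tau_E",
               "tau_A", "beta", "readout_gain")) {
    g_an <- res$grads[[nm]]
    idx <- seq_along(p[[nm]])
    if (nm %in% c("W_EE", "W_IE")) {
      idx <- which(p$masks[[sub("W_", "", nm)]] == 1)
    }
    for (i in idx) {
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (wg(p1)$loss - wg(p2)$loss) / (2 * eps)
      expect_equal(as.numeric(g_an[i]), fd, tolerance = 1e-5)
    }
  }
})

test_that("parameter checkpoints round-trip through JSON", {
  p <- tiny_params(5, 2, seed = 11, density = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_birnn_params(p, path)
  q <- read_birnn_params(path)
  for (nm in c("W_EE", "W_EI", "W_IE", "W_net", "b_net", "gain_net",
               "tau_E", "tau_I", "tau_A", "beta", "readout_gain",
               "readout_offset", "dt")) {
    expect_equal(unname(as.matrix(q[[nm]])), unname(as.matrix(p[[nm]])),
                 tolerance = 1e-12)
  }
  expect_equal(q$masks$EE, p$masks$EE, ignore_attr = TRUE)
})
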