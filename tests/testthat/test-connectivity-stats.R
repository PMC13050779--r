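test_that("connectivity extraction copies W_net under the target-source convention", {
  p <- tiny_params(8, 4, seed = 1)
  p$W_net <- diag(4)
  cm <- extract_network_connectivity(p, network_names = c("DMN", "TPN", "SN", "Other"))
  expect_equal(unclass(cm)[, ], diag(4), ignore_attr = TRUE)

  p$W_net[2, 3] <- 1.4 # source SN (col 3) -> target TPN (row 2)
  cm2 <- extract_network_connectivity(p, network_names = c("DMN", "TPN", "SN", "Other"))
  expect_equal(cm2["TPN", "SN"], 1.4)
  td <- tidy(cm2)
  expect_equal(td$weight[td$source == "SN" & td$target == "TPN"], 1.4)
  expect_equal(nrow(td), 16)

  expect_identical(extract_network_connectivity(p), extract_network_connectivity(p))
  p$W_net[1, 1] <- NaN
  expect_error(extract_network_connectivity(p), class = "birnn_extraction_error")
})

test_that("group tests match the textbook one-sample t and flag degeneracies", {
  vals <- matrix(0, 5, 16)
  vals[, 1] <- c(2.1, 1.9, 2.0, 2.2, 1.8) # cell (DMN <- DMN)
  vals[, 2] <- 1                          # constant nonzero: degenerate
  vals[1:2, 3] <- c(0.5, -0.5)            # mean zero with variance (n=5 incl 0s)
  set.seed(9)
  vals[, 5:16] <- rnorm(5 * 12, 0, 0.5)
  tab <- group_connection_tests(matrices_from_values(vals))
  expect_equal(nrow(tab), 16)
  expect_true(all(tab$p.adjusted >= tab$p.value - 1e-15))
  expect_true(all(tab$p.adjusted <= 1))

  r1 <- tab[tab$source == "DMN" & tab$target == "DMN", ]
  expect_equal(r1$mean, 2)
  expect_equal(r1$statistic, 2 / (sd(c(2.1, 1.9, 2, 2.2, 1.8)) / sqrt(5)),
               tolerance = 1e-12) # = 28.2843
  expect_equal(r1$df, 4)

  r2 <- tab[tab$source == "DMN" & tab$target == "TPN", ]
  expect_true(r2$degenerate)
  expect_equal(r2$p.value, 0)

  # exactly balanced two-subject cell: t = 0, p = 1
  two <- matrices_from_values(rbind(rep(0.5, 16), rep(-0.5, 16)))
  tab2 <- group_connection_tests(two)
  expect_true(all(tab2$statistic == 0))
  expect_true(all(tab2$p.value == 1))

  # all-zero cell convention
  zero <- matrices_from_values(matrix(0, 3, 16))
  tab0 <- group_connection_tests(zero)
  expect_true(all(tab0$p.value == 1))
  expect_false(any(tab0$degenerate))
  expect_false(any(tab0$significant))

  expect_error(group_connection_tests(matrices_from_values(vals)[1]),
               class = "birnn_shape_error")
})

test_that("FDR adjustment matches the brute-force step-up enumeration", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), class = "birnn_domain_error")
  expect_error(benjamini_hochberg(c(-0.1, 0.5)), class = "birnn_domain_error")

  set.seed(11)
  for (i in 1:50) {
    p <- runif(16)
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-14)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("FDR adjustment is permutation-equivariant and scaling-monotone", {
  set.seed(3)
  p <- runif(16, 0, 0.2)
  perm <- sample(16)
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))

  n_disc <- function(x) sum(benjamini_hochberg(x) < 0.05)
  for (f in c(1.5, 2, 5)) {
    expect_lte(n_disc(pmin(p * f, 1)), n_disc(p))
  }
})

test_that("cohort summaries equal per-cell recomputation", {
  one <- matrices_from_values(matrix(rnorm(16), 1, 16))
  s1 <- summarize_connectivity(one)
  expect_equal(s1$mean, s1$median)

  two <- matrices_from_values(rbind(rep(1, 16), rep(2, 16)))
  expect_true(all(summarize_connectivity(two)$mean == 1.5))

  set.seed(5)
  vals <- matrix(rnorm(15 * 16), 15, 16)
  s15 <- summarize_connectivity(matrices_from_values(vals))
  # brute-force oracle in (target, source) vectorized cell order
  nm <- c("DMN", "TPN", "SN", "Other")
  for (cell in 1:16) {
    i <- (cell - 1) %% 4 + 1; j <- (cell - 1) %/% 4 + 1
    row <- s15[s15$target == nm[i] & s15$source == nm[j], ]
    expect_equal(row$mean, mean(vals[, cell]))
    expect_equal(row$median, median(vals[, cell]))
  }
  expect_error(summarize_connectivity(list()), class = "birnn_empty_cohort_error")

  wide <- summarize_connectivity(
    c(matrices_from_values(vals, "task"), matrices_from_values(vals, "rest")),
    wide = TRUE)
  expect_equal(nrow(wide), 16)
  expect_true(all(c("task_mean", "task_median", "rest_mean", "rest_median")
                  %in% names(wide)))
})

test_that("imagery association is exact for monotone data and r^2-consistent", {
  w <- c(1, 2, 3, 5, 8, 13, 21)
  sc <- 2 * w + 3
  fit <- imagery_regression(w, sc)
  expect_equal(fit$r, 1)
  expect_equal(fit$r.squared, 1)

  set.seed(2)
  w2 <- rnorm(15); sc2 <- rnorm(15)
  for (m in c("spearman", "ols")) {
    f <- imagery_regression(w2, sc2, method = m)
    expect_equal(f$r^2, f$r.squared)
  }
  ols <- imagery_regression(w2, sc2, method = "ols")
  lmfit <- lm(sc2 ~ w2)
  expect_equal(ols$r.squared, summary(lmfit)$r.squared)
  expect_equal(ols$p.value, summary(lmfit)$coefficients[2, 4])

  expect_error(imagery_regression(rep(1, 15), sc2),
               class = "birnn_degenerate_error")
  expect_error(imagery_regression(w2[1:3], sc2[1:3]),
               class = "birnn_shape_error")

  # family of couplings corrected by the Hochberg step-up procedure
  fam <- imagery_regression(data.frame(a = w2, b = rnorm(15), c = rnorm(15)),
                            sc2)
  expect_equal(fam$p.adjusted, p.adjust(fam$p.value, method = "hochberg"))
  one <- imagery_regression(w2, sc2, n_tests = 4)
  expect_equal(one$p.adjusted, min(1, 4 * one$p.value))
})

test_that("the rank-based R^2 is calibrated under the null", {
  set.seed(17)
  reps <- 400
  r2 <- numeric(reps); rej <- logical(reps)
  for (i in 1:reps) {
    f <- imagery_regression(rnorm(15), rnorm(15), n_tests = 2)
    r2[i] <- f$r.squared
    rej[i] <- f$p.adjusted < 0.05
  }
  expect_lt(mean(r2), 0.15)       # no spurious explained variance
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / reps)) # <= nominal
})

test_that("planted nonzero-mean cells are recovered by the group tests", {
  set.seed(23)
  planted <- c(1, 6, 7, 10, 13, 16) # 6 of 16 cells
  hits <- fps <- numeric(50)
  for (r in 1:50) {
    vals <- matrix(rnorm(15 * 16, 0, 0.3), 15, 16)
    vals[, planted] <- vals[, planted] + 0.45 # effect size d = 1.5
    tab <- group_connection_tests(matrices_from_values(vals))
    nm <- c("DMN", "TPN", "SN", "Other")
    cell_id <- (match(tab$source, nm) - 1) * 4 + match(tab$target, nm)
    hits[r] <- sum(tab$significant[cell_id %in% planted])
    fps[r] <- sum(tab$significant[!cell_id %in% planted])
  }
  expect_gte(mean(hits >= 5 & fps <= 1), 0.9)
})
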