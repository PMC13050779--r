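#' Granger F-test for one directed pair at a fixed lag
#'
#' Fits two nested autoregressions by least squares on the same target
#' samples: a restricted model (target on its own `lag` past values plus an
#' intercept) and a full model adding the source's `lag` past values. The
#' F-test on the joint contribution of the lagged source coefficients has
#' `(lag, T_eff - 2 lag - 1)` degrees of freedom with `T_eff = T - lag`
#' effective samples.
#'
#' @param source,target Numeric time series of equal length.
#' @param lag Number of past values (VAR order) to include.
#' @return One-row tibble: `lag`, `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
granger_test <- function(source, target, lag) {
  Tn <- length(target)
  stopifnot(length(source) == Tn, lag >= 1)
  if (Tn - lag <= 2 * lag + 1) {
    abort("insufficient samples for this lag.", class = "birnn_length_error")
  }
  y <- target[(lag + 1):Tn]
  lag_mat <- function(x) {
    sapply(seq_len(lag), function(k) x[(lag + 1 - k):(Tn - k)])
  }
  Xr <- cbind(1, lag_mat(target))
  Xf <- cbind(Xr, lag_mat(source))
  if (qr(Xf)$rank < ncol(Xf)) {
    abort("singular design (constant or collinear series).",
          class = "birnn_rank_error")
  }
  rss <- function(X) {
    f <- stats::.lm.fit(X, y)
    sum(f$residuals^2)
  }
  rss_r <- rss(Xr); rss_f <- rss(Xf)
  df2 <- length(y) - 2 * lag - 1
  f_stat <- ((rss_r - rss_f) / lag) / (rss_f / df2)
  tibble::tibble(lag = lag, statistic = f_stat, df1 = lag, df2 = df2,
                 p.value = pf(f_stat, lag, df2, lower.tail = FALSE))
}

#' Pairwise Granger causality over network time series
#'
#' For every ordered pair of networks (source j, target i) and every lag in
#' `1..max_lag`, runs the nested-VAR F-test of [granger_test()] and keeps the
#' lag with the minimum p-value. The selected F statistic lands at position
#' (i, j) of a directed matrix; diagonal self-connections are undefined and
#' set to zero by convention. Note the min-p selection across lags is
#' reported as-is, uncorrected for the multiplicity across lags (use
#' `keep_all_lags` to retain every per-lag result).
#'
#' @param network_series Networks x samples numeric matrix (e.g. from
#'   [aggregate_parcels_to_networks()]), rownames used as network labels.
#' @param max_lag Largest VAR order tested (default 10).
#' @param keep_all_lags Also return the per-lag table?
#' @param subject_id,condition Metadata.
#' @return A `granger_result`: `f_matrix`, `p_matrix`, `lag_matrix`
#'   (minimum-p lag per pair), metadata, and optionally `all_lags`.
#' @export
pairwise_granger <- function(network_series, max_lag = 10,
                             keep_all_lags = FALSE,
                             subject_id = NA_character_,
                             condition = NA_character_) {
  M <- as.matrix(network_series)
  K <- nrow(M); Tn <- ncol(M)
  if (Tn <= 10 * max_lag) {
    abort("series too short for the requested max_lag.",
          class = "birnn_length_error")
  }
  nm <- rownames(M) %||% paste0("net", seq_len(K))
  f_matrix <- p_matrix <- matrix(0, K, K, dimnames = list(target = nm, source = nm))
  lag_matrix <- matrix(NA_integer_, K, K, dimnames = list(target = nm, source = nm))
  all_lags <- list()
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i == j) next
      per_lag <- purrr::map_dfr(seq_len(max_lag), function(k)
        granger_test(M[j, ], M[i, ], k))
      pick <- which.min(per_lag$p.value)
      f_matrix[i, j] <- per_lag$statistic[pick]
      p_matrix[i, j] <- per_lag$p.value[pick]
      lag_matrix[i, j] <- per_lag$lag[pick]
      if (keep_all_lags) {
        all_lags[[length(all_lags) + 1L]] <-
          dplyr::mutate(per_lag, source = nm[j], target = nm[i],
                        .before = 1)
      }
    }
  }
  structure(
    list(f_matrix = f_matrix, p_matrix = p_matrix, lag_matrix = lag_matrix,
         max_lag = max_lag, network_names = nm, subject_id = subject_id,
         condition = condition,
         all_lags = if (keep_all_lags) dplyr::bind_rows(all_lags)),
    class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("<granger_result> subject %s, condition %s | lags 1-%d (min-p selection)\n",
              x$subject_id, x$condition, x$max_lag))
  print(round(x$f_matrix, 2))
  invisible(x)
}

#' Tidy a Granger result into one row per directed pair
#'
#' @param x A `granger_result`.
#' @param ... Unused.
#' @return Tibble with `source`, `target`, `statistic` (F), `p.value`,
#'   `lag`, metadata; self-connections excluded.
#' @export
tidy.granger_result <- function(x, ...) {
  nm <- x$network_names
  K <- length(nm)
  tibble::tibble(
    target = rep(nm, times = K), source = rep(nm, each = K),
    statistic = as.vector(x$f_matrix), p.value = as.vector(x$p_matrix),
    lag = as.vector(x$lag_matrix),
    subject_id = x$subject_id, condition = x$condition) |>
    dplyr::filter(.data$source != .data$target) |>
    dplyr::select("source", "target", "statistic", "p.value", "lag",
                  "subject_id", "condition")
}

#' Group-level tests on Granger F matrices
#'
#' Averages subject-level F matrices entrywise and runs one-sample t-tests
#' per off-diagonal directed pair (12 cells for 4 networks), with
#' Benjamini-Hochberg FDR over the cells within each condition -- the same
#' machinery used for the model-based couplings. F statistics are
#' nonnegative, so this follows the convention of testing mean F against
#' zero.
#'
#' @param results List of `granger_result` objects (>= 2 subjects).
#' @param q FDR threshold for the significance flag.
#' @return Tibble in the same layout as [group_connection_tests()] (off-
#'   diagonal cells only), plus the group-mean F per cell.
#' @export
group_granger_tests <- function(results, q = 0.05) {
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, TRUE, "granger_result")))
  nm <- results[[1]]$network_names
  long <- purrr::map_dfr(results, tidy)
  long |>
    dplyr::group_by(.data$condition, .data$source, .data$target) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$statistic),
      median = median(.data$statistic), sd = sd(.data$statistic),
      test = list(one_sample_cell_test(.data$statistic)), .groups = "drop") |>
    tidyr::unnest("test", names_sep = ".") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(p.adjusted = benjamini_hochberg(.data$test.p.value)) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      condition = .data$condition, source = .data$source,
      target = .data$target, n = .data$n, mean = .data$mean,
      median = .data$median, sd = .data$sd,
      statistic = .data$test.statistic, df = .data$test.df,
      p.value = .data$test.p.value, p.adjusted = .data$p.adjusted,
      significant = .data$p.adjusted < q,
      degenerate = .data$test.degenerate)
}
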