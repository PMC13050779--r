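#' Extract the learned network-to-network coupling
#'
#' Copies the fitted `W_net` into a labelled `connectivity_matrix` with the
#' (target, source) orientation convention: entry (i, j) is the directed,
#' signed influence of network j on network i. No transformation is applied to
#' the values.
#'
#' @param x A `birnn_fit` or [birnn_params()] object.
#' @param subject_id,condition Metadata overrides (taken from the fit when
#'   available).
#' @param network_names Labels for rows/columns.
#' @return A `connectivity_matrix` (numeric matrix with metadata attributes).
#' @export
extract_network_connectivity <- function(x, subject_id = NULL,
                                         condition = NULL,
                                         network_names = NULL) {
  if (inherits(x, "birnn_fit")) {
    subject_id <- subject_id %||% x$subject_id
    condition <- condition %||% x$condition
    network_names <- network_names %||% x$projection$network_names
    params <- x$params
  } else {
    params <- x
    network_names <- network_names %||% params$network_names %||%
      paste0("net", seq_len(params$n_networks))
  }
  w <- params$W_net
  if (any(!is.finite(w))) {
    abort("W_net contains non-finite values (untrained or diverged model).",
          class = "birnn_extraction_error")
  }
  connectivity_matrix(w, network_names = network_names,
                      subject_id = subject_id %||% NA_character_,
                      condition = condition %||% NA_character_)
}

#' Construct a labelled connectivity matrix
#'
#' @param values Square numeric matrix; entry (i, j) is the influence of
#'   network j (source) on network i (target).
#' @param network_names Network labels.
#' @param subject_id,condition Metadata.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values,
                                network_names = c("DMN", "TPN", "SN", "Other"),
                                subject_id = NA_character_,
                                condition = NA_character_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values),
            nrow(values) == length(network_names))
  check_finite_matrix(values, "values")
  dimnames(values) <- list(target = network_names, source = network_names)
  structure(values, class = c("connectivity_matrix", "matrix"),
            network_names = network_names, subject_id = subject_id,
            condition = condition)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> subject %s, condition %s (rows = target, cols = source)\n",
              attr(x, "subject_id"), attr(x, "condition")))
  print(unclass_cm(x))
  invisible(x)
}

unclass_cm <- function(x) {
  y <- unclass(x)
  attributes(y)[c("network_names", "subject_id", "condition")] <- NULL
  y
}

#' Tidy a connectivity matrix into one row per directed coupling
#'
#' @param x A [connectivity_matrix()].
#' @param ... Unused.
#' @return Tibble with `source`, `target`, `weight`, `subject_id`,
#'   `condition`.
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  nm <- attr(x, "network_names")
  tibble::tibble(
    target = rep(nm, times = length(nm)),
    source = rep(nm, each = length(nm)),
    weight = as.vector(unclass_cm(x)),
    subject_id = attr(x, "subject_id"),
    condition = attr(x, "condition")) |>
    dplyr::select("source", "target", "weight", "subject_id", "condition")
}

cohort_long <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "connectivity_matrix")))
  nm <- attr(matrices[[1]], "network_names")
  ok <- vapply(matrices, function(m)
    identical(attr(m, "network_names"), nm), TRUE)
  if (!all(ok)) {
    abort("inconsistent network ordering across subjects.",
          class = "birnn_alignment_error")
  }
  purrr::map_dfr(matrices, tidy)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending, the adjusted value at
#' rank k is `min over j >= k of (m * p_(j) / j)`, capped at 1 and returned in
#' the original order.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order, elementwise `>=` the raw values.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1].", class = "birnn_domain_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

one_sample_cell_test <- function(values) {
  n <- length(values)
  if (sd(values) == 0) {
    if (all(values == 0)) {
      return(tibble::tibble(estimate = 0, statistic = 0, df = n - 1,
                            p.value = 1, degenerate = FALSE))
    }
    # nonzero constant: t undefined; report the limiting p and flag the row
    return(tibble::tibble(estimate = mean(values), statistic = Inf * sign(mean(values)),
                          df = n - 1, p.value = 0, degenerate = TRUE))
  }
  tt <- t.test(values, mu = 0)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value,
                 degenerate = FALSE)
}

#' Group-level one-sample tests over all network couplings
#'
#' For each of the 16 directed couplings, tests whether the mean coupling
#' strength across subjects differs from zero (two-sided one-sample t-test),
#' then applies Benjamini-Hochberg FDR correction over the 16 tests within
#' each condition and flags couplings with adjusted p below `q`.
#'
#' Cells with zero across-subject variance are degenerate: all-zero cells get
#' `t = 0, p = 1` by convention; constant nonzero cells are flagged
#' (`degenerate = TRUE`) with the limiting `p = 0`.
#'
#' @param matrices List of [connectivity_matrix()] objects (>= 2 subjects),
#'   possibly spanning several conditions.
#' @param q FDR threshold for the significance flag (default 0.05).
#' @return Tibble with one row per coupling (per condition): source, target,
#'   group mean/median/sd, t statistic, degrees of freedom, raw and
#'   FDR-adjusted p, significance flag, degeneracy flag, n subjects.
#' @export
group_connection_tests <- function(matrices, q = 0.05) {
  long <- cohort_long(matrices)
  if (dplyr::n_distinct(long$subject_id) < 2) {
    abort("need at least 2 subjects.", class = "birnn_shape_error")
  }
  long |>
    dplyr::group_by(.data$condition, .data$source, .data$target) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$weight), median = median(.data$weight),
      sd = sd(.data$weight), test = list(one_sample_cell_test(.data$weight)),
      .groups = "drop") |>
    tidyr::unnest("test", names_sep = ".") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(p.adjusted = benjamini_hochberg(.data$test.p.value)) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      condition = .data$condition, source = .data$source,
      target = .data$target, n = .data$n, mean = .data$mean,
      median = .data$median, sd = .data$sd, statistic = .data$test.statistic,
      df = .data$test.df, p.value = .data$test.p.value,
      p.adjusted = .data$p.adjusted,
      significant = .data$p.adjusted < q,
      degenerate = .data$test.degenerate)
}

#' Mean/median coupling strengths across a cohort
#'
#' Entrywise group mean and median per directed coupling and condition, the
#' standard summary table layout for this analysis.
#'
#' @param matrices List of [connectivity_matrix()] objects (>= 1 subject).
#' @param wide Pivot conditions into side-by-side `mean`/`median` column
#'   pairs (one row per coupling)?
#' @return A tibble.
#' @export
summarize_connectivity <- function(matrices, wide = FALSE) {
  if (length(matrices) == 0) {
    abort("empty cohort.", class = "birnn_empty_cohort_error")
  }
  out <- cohort_long(matrices) |>
    dplyr::group_by(.data$condition, .data$source, .data$target) |>
    dplyr::summarise(mean = mean(.data$weight), median = median(.data$weight),
                     .groups = "drop") |>
    dplyr::mutate(connection = paste(.data$source, "→", .data$target))
  if (!wide) return(out)
  out |>
    tidyr::pivot_wider(id_cols = c("connection", "source", "target"),
                       names_from = "condition",
                       values_from = c("mean", "median"),
                       names_glue = "{condition}_{.value}")
}

#' Association between a coupling strength and a behavioral covariate
#'
#' Robust rank-based association between per-subject coupling weights and a
#' covariate (e.g. an imagery-vividness score): the correlation is Spearman's
#' r_s (sign-matched to the monotone trend) and `r.squared = r_s^2`, the
#' variance in score ranks explained by a monotone transform of the weights.
#' An ordinary least-squares route (`method = "ols"`, Pearson r, linear R^2)
#' is also available. The family of raw p-values across couplings is
#' corrected by the Hochberg step-up procedure (the standard referent of the
#' compound name "Simes-Bonferroni").
#'
#' @param weights Numeric vector of per-subject coupling weights, or a data
#'   frame / named list of several coupling columns tested as one family.
#' @param scores Numeric per-subject covariate (same length).
#' @param method `"spearman"` (default) or `"ols"`.
#' @param n_tests Family size for the correction when a single coupling is
#'   supplied (a lone smallest p in a family of m gets `min(1, m p)`); when
#'   several couplings are supplied the Hochberg procedure runs over all of
#'   them and `n_tests` is ignored.
#' @return Tibble with one row per coupling: `term`, `n`, `r`, `r.squared`,
#'   `p.value`, `p.adjusted`, `method`.
#' @export
imagery_regression <- function(weights, scores, method = c("spearman", "ols"),
                               n_tests = 1) {
  method <- match.arg(method)
  wlist <- if (is.data.frame(weights) || (is.list(weights) && !is.numeric(weights))) {
    lapply(weights, as.numeric)
  } else {
    list(coupling = as.numeric(weights))
  }
  if (is.null(names(wlist)) || any(names(wlist) == "")) {
    names(wlist) <- paste0("coupling", seq_along(wlist))
  }
  scores <- as.numeric(scores)
  rows <- purrr::imap_dfr(wlist, function(w, nm) {
    if (length(w) != length(scores) || length(w) < 4) {
      abort("weights and scores must have equal length >= 4.",
            class = "birnn_shape_error")
    }
    if (anyNA(w) || anyNA(scores)) {
      abort("missing values are not allowed.", class = "birnn_domain_error")
    }
    if (sd(w) == 0) {
      abort("constant coupling weights: degenerate predictor.",
            class = "birnn_degenerate_error")
    }
    if (method == "spearman") {
      ct <- suppressWarnings(
        stats::cor.test(w, scores, method = "spearman", exact = FALSE))
      r <- unname(ct$estimate)
    } else {
      fit <- stats::lm(scores ~ w)
      r <- unname(sign(stats::coef(fit)[2])) * sqrt(summary(fit)$r.squared)
      ct <- list(p.value = summary(fit)$coefficients[2, 4])
    }
    tibble::tibble(term = nm, n = length(w), r = r, r.squared = r^2,
                   p.value = ct$p.value, method = method)
  })
  if (nrow(rows) > 1) {
    rows$p.adjusted <- stats::p.adjust(rows$p.value, method = "hochberg")
  } else {
    rows$p.adjusted <- pmin(1, n_tests * rows$p.value)
  }
  rows[c("term", "n", "r", "r.squared", "p.value", "p.adjusted", "method")]
}
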