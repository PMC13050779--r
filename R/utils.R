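#' Logistic sigmoid
#'
#' Converts synaptic input into a bounded population firing rate in (0, 1).
#'
#' @param x Numeric vector or matrix.
#' @return Object of the same shape with values `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Inverse-solution regularization constant from an assumed SNR
#'
#' Distributed EEG inverse solutions are regularized by a constant tied to the
#' assumed sensor signal-to-noise ratio: `lambda^2 = 1 / snr^2`. An SNR of 3
#' gives 0.111 (to three decimals), the conventional broadband default.
#'
#' @param snr Assumed amplitude signal-to-noise ratio; must be positive.
#' @return The scalar regularization constant `1 / snr^2`.
#' @examples
#' inverse_regularization_from_snr(3)
#' @export
inverse_regularization_from_snr <- function(snr) {
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0) {
    abort("`snr` must be a single positive number.", class = "birnn_domain_error")
  }
  1 / snr^2
}

#' Recall performance as a percentage of list length
#'
#' @param items_recalled Mean number of items recalled.
#' @param list_length Number of items in the studied list.
#' @param digits Rounding for the printed percentage (default whole percent).
#' @return Percentage of the list recalled.
#' @examples
#' recall_percent(12, 16) # 75
#' @export
recall_percent <- function(items_recalled, list_length, digits = 0) {
  stopifnot(is.numeric(items_recalled), is.numeric(list_length), all(list_length > 0))
  round(100 * items_recalled / list_length, digits)
}

#' Variance explained from a correlation coefficient
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param digits Rounding applied to `r^2` (default two decimals, the usual
#'   reporting precision).
#' @return `r^2`, rounded.
#' @examples
#' r_to_r_squared(0.64) # 0.41
#' @export
r_to_r_squared <- function(r, digits = 2) {
  stopifnot(is.numeric(r), all(abs(r) <= 1))
  round(r^2, digits)
}

# derive a reproducible child seed (kept under 2^31) from a base seed and keys
derive_seed <- function(seed, ...) {
  keys <- c(seed, unlist(lapply(list(...), function(k) {
    if (is.character(k)) sum(utf8ToInt(k)) else as.numeric(k)
  })))
  x <- 0
  for (k in keys) x <- (x * 69069 + as.numeric(k) * 7919 + 1) %% 2147483629
  as.integer(x)
}

check_finite_matrix <- function(m, what) {
  if (!all(is.finite(m))) {
    abort(paste0("`", what, "` contains non-finite values."),
          class = "birnn_numeric_error")
  }
  invisible(m)
}
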