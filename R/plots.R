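#' Heatmap of a signed directed coupling matrix
#'
#' @param object A [connectivity_matrix()].
#' @param ... Unused.
#' @return A ggplot: sources on the x axis, targets on the y axis, diverging
#'   fill centered at zero (red facilitation, blue inhibition).
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  df <- tidy(object)
  nm <- attr(object, "network_names")
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$source, nm), y = factor(.data$target, rev(nm)),
    fill = .data$weight)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$weight)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = "source network", y = "target network",
                  fill = "coupling",
                  title = sprintf("Directed network coupling (%s)",
                                  attr(object, "condition"))) +
    ggplot2::theme_minimal()
}

#' Training curves of a fitted model
#'
#' @param object A `birnn_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch with the restored best
#'   epoch marked.
#' @export
autoplot.birnn_fit <- function(object, ...) {
  df <- object$history |>
    dplyr::select("epoch", train = "train_mse", validation = "val_loss") |>
    tidyr::pivot_longer(-"epoch", names_to = "split", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mse,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "one-step MSE",
                  title = sprintf("Training history (%s, %s)",
                                  object$subject_id, object$condition)) +
    ggplot2::theme_minimal()
}

#' Significance profile of group-level coupling tests
#'
#' Shows each directed coupling's -log10 FDR-adjusted p (a monotone transform
#' preserving the significance ordering), with the q threshold as a dashed
#' line.
#'
#' @param stats Output of [group_connection_tests()] or
#'   [group_granger_tests()].
#' @param q Threshold drawn as the dashed line.
#' @return A ggplot.
#' @export
plot_significance <- function(stats, q = 0.05) {
  df <- stats |>
    dplyr::mutate(connection = paste(.data$source, "→", .data$target),
                  neglogp = -log10(pmax(.data$p.adjusted, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$connection, .data$neglogp),
    y = .data$neglogp, fill = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(q), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "grey90",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "adjusted p"),
                  fill = "group mean") +
    ggplot2::theme_minimal()
}
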