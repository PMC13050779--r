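#' Fixed parcel-to-network projection
#'
#' Builds the fixed matrices that tie cortical parcels to canonical large-scale
#' networks. `W_in` (networks x parcels) projects parcel activity into network
#' space with each row normalized to sum to one, so a network signal is the
#' mean of its member parcels and amplitudes stay comparable across networks of
#' different sizes. `W_out_pattern` (parcels x networks) is the membership
#' indicator used for uniform top-down feedback; a per-network learnable gain
#' scales it inside the model.
#'
#' @param membership Data frame with columns `parcel_id` and `network`. Every
#'   parcel must be assigned to exactly one of `network_names`.
#' @param network_names Ordered network labels (default the triple-network
#'   systems plus a catch-all: DMN, TPN, SN, Other).
#' @return A `network_projection` object with elements `membership`, `W_in`,
#'   `W_out_pattern`, `network_names`, `parcel_ids`, and `net_index` (1-based
#'   network index per parcel).
#' @examples
#' m <- data.frame(parcel_id = c("p1", "p2", "p3"),
#'                 network = c("DMN", "DMN", "SN"))
#' pr <- network_projection(m, network_names = c("DMN", "SN"))
#' rowSums(pr$W_in)
#' @export
network_projection <- function(membership,
                               network_names = c("DMN", "TPN", "SN", "Other")) {
  stopifnot(is.data.frame(membership),
            all(c("parcel_id", "network") %in% names(membership)))
  membership <- tibble::as_tibble(membership) |>
    dplyr::mutate(parcel_id = as.character(.data$parcel_id),
                  network = as.character(.data$network))
  if (anyNA(membership$network) || any(membership$network == "")) {
    abort("unassigned parcel in membership table.",
          class = "birnn_assignment_error")
  }
  unknown <- setdiff(membership$network, network_names)
  if (length(unknown) > 0) {
    abort(paste0("unknown network label(s): ", paste(unknown, collapse = ", ")),
          class = "birnn_label_error")
  }
  if (anyDuplicated(membership$parcel_id)) {
    abort("each parcel must be assigned exactly once.",
          class = "birnn_assignment_error")
  }
  P <- nrow(membership)
  K <- length(network_names)
  net_index <- match(membership$network, network_names)
  W_out_pattern <- matrix(0, P, K,
                          dimnames = list(membership$parcel_id, network_names))
  W_out_pattern[cbind(seq_len(P), net_index)] <- 1
  sizes <- colSums(W_out_pattern)
  if (any(sizes == 0)) {
    abort(paste0("network with no member parcels: ",
                 paste(network_names[sizes == 0], collapse = ", ")),
          class = "birnn_assignment_error")
  }
  W_in <- t(W_out_pattern) / sizes # each row sums to 1: network = parcel mean
  structure(
    list(membership = membership, W_in = W_in, W_out_pattern = W_out_pattern,
         network_names = network_names, parcel_ids = membership$parcel_id,
         net_index = net_index),
    class = "network_projection"
  )
}

#' @export
print.network_projection <- function(x, ...) {
  sizes <- table(factor(x$membership$network, levels = x$network_names))
  cat(sprintf("<network_projection> %d parcels -> %d networks (%s)\n",
              length(x$parcel_ids), length(x$network_names),
              paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' Read a parcel-to-network membership table
#'
#' @param path Two-column CSV (`parcel_id`, `network`).
#' @param ... Passed to [network_projection()].
#' @return A `network_projection` object.
#' @export
read_membership <- function(path, ...) {
  network_projection(readr::read_csv(path, col_types = "cc"), ...)
}

#' Packaged default 46-parcel membership (synthetic stand-in)
#'
#' The published 46-parcel bilateral atlas-to-network table is not publicly
#' deposited, so the package ships a synthetic stand-in with 46 plausible
#' bilateral parcel labels split across DMN (12), TPN (14), SN (8), and Other
#' (12). Supply your own table via [read_membership()] for real analyses.
#'
#' @return A `network_projection` over 46 synthetic parcels.
#' @export
default_projection <- function() {
  read_membership(system.file("extdata", "parcels_synthetic_46.csv",
                              package = "birnn"))
}

#' Synthetic membership for arbitrary sizes
#'
#' Round-robin assignment of `n_parcels` placeholder parcels to the network
#' labels; used to build reduced-size fixtures.
#'
#' @param n_parcels Number of parcels.
#' @param network_names Network labels.
#' @return A `network_projection`.
#' @export
synthetic_membership <- function(n_parcels,
                                 network_names = c("DMN", "TPN", "SN", "Other")) {
  network_projection(
    tibble::tibble(
      parcel_id = sprintf("parcel_%02d", seq_len(n_parcels)),
      network = rep(network_names, length.out = n_parcels)),
    network_names = network_names)
}

#' Aggregate parcel series to network series
#'
#' Applies the fixed `W_in` projection, so each network signal is the mean of
#' its member parcels at every sample.
#'
#' @param series A [parcel_ts()] object.
#' @param projection A [network_projection()] whose parcel ordering matches
#'   `series`.
#' @return Numeric matrix, networks x samples, with network rownames.
#' @export
aggregate_parcels_to_networks <- function(series, projection) {
  stopifnot(inherits(series, "parcel_ts"), inherits(projection, "network_projection"))
  if (!identical(series$parcel_ids, projection$parcel_ids)) {
    abort("parcel ordering of series does not match the projection.",
          class = "birnn_alignment_error")
  }
  projection$W_in %*% series$values
}
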