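#' Parcel-level source-activity time series
#'
#' Container for one recording: a parcels-by-samples matrix of source-localized
#' activity plus sampling metadata. Rows are cortical parcels (atlas regions
#' whose voxel-level source time courses were averaged into one signal each);
#' columns are time samples.
#'
#' @param values Numeric matrix, parcels in rows, samples in columns.
#' @param parcel_ids Character vector of parcel labels, one per row.
#' @param sampling_rate Samples per second (default 1000, the acquisition rate
#'   the model's 1 ms integration step assumes).
#' @param subject_id Subject label.
#' @param condition One of `"rest"`, `"task"`, `"task_shapes"`, `"task_words"`.
#' @return A `parcel_ts` object.
#' @examples
#' x <- parcel_ts(matrix(rnorm(20), 2, 10), c("p1", "p2"))
#' dim(x$values)
#' @export
parcel_ts <- function(values, parcel_ids = rownames(values),
                      sampling_rate = 1000, subject_id = "s01",
                      condition = c("rest", "task", "task_shapes", "task_words")) {
  condition <- match.arg(condition)
  values <- as.matrix(values)
  if (is.null(parcel_ids)) {
    parcel_ids <- paste0("parcel_", seq_len(nrow(values)))
  }
  if (length(parcel_ids) != nrow(values)) {
    abort("`parcel_ids` length must match the number of rows in `values`.",
          class = "birnn_shape_error")
  }
  if (ncol(values) < 2) {
    abort("a parcel time series needs at least 2 samples.",
          class = "birnn_shape_error")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be positive.", class = "birnn_domain_error")
  }
  check_finite_matrix(values, "values")
  rownames(values) <- parcel_ids
  structure(
    list(values = values, parcel_ids = as.character(parcel_ids),
         sampling_rate = sampling_rate, subject_id = subject_id,
         condition = condition),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf(
    "<parcel_ts> %d parcels x %d samples @ %g Hz | subject %s, condition %s\n",
    nrow(x$values), ncol(x$values), x$sampling_rate, x$subject_id, x$condition))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$values)

#' Tidy a parcel time series into long form
#'
#' @param x A [parcel_ts()] object.
#' @param ... Unused.
#' @return A tibble with columns `parcel_id`, `time_s`, `value`, `subject_id`,
#'   `condition`.
#' @export
tidy.parcel_ts <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "parcel_id", .name_repair = "minimal") |>
    rlang::set_names(c("parcel_id", seq_len(ncol(x$values)))) |>
    tidyr::pivot_longer(-"parcel_id", names_to = "sample", values_to = "value") |>
    dplyr::mutate(
      sample = as.integer(.data$sample),
      time_s = (.data$sample - 1) / x$sampling_rate,
      subject_id = x$subject_id, condition = x$condition
    ) |>
    dplyr::select("parcel_id", "sample", "time_s", "value", "subject_id",
                  "condition")
}

#' Read a parcel time series from CSV/TSV
#'
#' Expects the on-disk layout written by [write_parcel_ts()]: first column
#' `parcel_id`, remaining columns one per sample. Values round-trip at full
#' stored precision.
#'
#' @param path File path.
#' @param sampling_rate,subject_id,condition Metadata attached to the result;
#'   see [parcel_ts()].
#' @param parcel_ids Optional expected parcel ordering; an error is raised if
#'   the file does not contain exactly these parcels in this order.
#' @return A [parcel_ts()] object.
#' @export
read_parcel_ts <- function(path, sampling_rate = 1000, subject_id = "s01",
                           condition = "rest", parcel_ids = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "birnn_io_error")
  }
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    parcel_id = readr::col_character(), .default = readr::col_character()))
  if (!"parcel_id" %in% names(raw)) {
    abort("expected a `parcel_id` header column.", class = "birnn_parse_error")
  }
  num <- as.matrix(raw[setdiff(names(raw), "parcel_id")])
  parsed <- suppressWarnings(array(as.numeric(num), dim = dim(num)))
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell at row %d, sample column %d.",
                  bad[1], bad[2]), class = "birnn_parse_error")
  }
  if (!is.null(parcel_ids) && !identical(as.character(raw$parcel_id),
                                         as.character(parcel_ids))) {
    abort("parcel ids in file do not match the expected atlas ordering.",
          class = "birnn_shape_error")
  }
  parcel_ts(parsed, parcel_ids = raw$parcel_id, sampling_rate = sampling_rate,
            subject_id = subject_id, condition = condition)
}

#' Write a parcel time series to CSV/TSV
#'
#' @param x A [parcel_ts()] object.
#' @param path Destination (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_parcel_ts <- function(x, path) {
  stopifnot(inherits(x, "parcel_ts"))
  df <- tibble::as_tibble(x$values, rownames = "parcel_id",
                          .name_repair = "minimal")
  names(df) <- c("parcel_id", paste0("t", seq_len(ncol(x$values))))
  if (grepl("\\.tsv$", path)) readr::write_tsv(df, path)
  else readr::write_csv(df, path)
  invisible(path)
}

#' Average voxel-level source series into parcel series
#'
#' Each parcel signal is the unweighted arithmetic mean of its member voxels'
#' series at every time point, preserving parcel-level fluctuations while
#' averaging out voxel-specific noise.
#'
#' @param voxel_values Numeric matrix, voxels in rows, samples in columns.
#' @param voxel_to_parcel Character/factor vector assigning each voxel row to a
#'   parcel, or a data frame with columns `voxel` (row index or name) and
#'   `parcel_id`.
#' @param ... Metadata passed to [parcel_ts()].
#' @return A [parcel_ts()] object with one row per parcel, parcels ordered by
#'   first appearance in the mapping.
#' @export
aggregate_voxels_to_parcels <- function(voxel_values, voxel_to_parcel, ...) {
  voxel_values <- as.matrix(voxel_values)
  if (is.data.frame(voxel_to_parcel)) {
    map <- as.character(voxel_to_parcel$parcel_id[
      order(match(voxel_to_parcel$voxel, seq_len(nrow(voxel_values))))])
  } else {
    map <- as.character(voxel_to_parcel)
  }
  if (length(map) != nrow(voxel_values)) {
    abort("every voxel row needs exactly one parcel assignment.",
          class = "birnn_shape_error")
  }
  parcels <- unique(map)
  if (anyNA(map)) {
    abort("voxel with missing parcel assignment.", class = "birnn_empty_parcel_error")
  }
  out <- matrix(0, length(parcels), ncol(voxel_values),
                dimnames = list(parcels, NULL))
  for (p in parcels) {
    rows <- which(map == p)
    if (length(rows) == 0) {
      abort(paste0("parcel with zero voxels: ", p),
            class = "birnn_empty_parcel_error")
    }
    out[p, ] <- colMeans(voxel_values[rows, , drop = FALSE])
  }
  parcel_ts(out, parcel_ids = parcels, ...)
}

#' Cut a recording into condition segments using an events table
#'
#' @param x A [parcel_ts()] object spanning a whole session.
#' @param events Data frame with columns `onset_s`, `offset_s`, `label`
#'   (labels must be valid [parcel_ts()] conditions).
#' @return A tibble with columns `condition` and `series` (list-column of
#'   [parcel_ts()] segments).
#' @export
segment_by_events <- function(x, events) {
  stopifnot(inherits(x, "parcel_ts"),
            all(c("onset_s", "offset_s", "label") %in% names(events)))
  purrr::pmap(events, function(onset_s, offset_s, label, ...) {
    i0 <- max(1L, floor(onset_s * x$sampling_rate) + 1L)
    i1 <- min(ncol(x$values), floor(offset_s * x$sampling_rate))
    if (i1 - i0 < 1) {
      abort("event segment shorter than 2 samples.", class = "birnn_shape_error")
    }
    parcel_ts(x$values[, i0:i1, drop = FALSE], x$parcel_ids,
              sampling_rate = x$sampling_rate, subject_id = x$subject_id,
              condition = label)
  }) |>
    (\(segs) tibble::tibble(condition = as.character(events$label),
                            series = segs))()
}
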