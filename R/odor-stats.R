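# Per-cluster odor-note profiles and note co-occurrence matrices.
#
# Two relative statistics describe how a note distributes over clusters:
#   %ON  = 100 * (occurrences of the note in the cluster) /
#                (occurrences of the note in the whole dataset)
#   %OM  = 100 * (occurrences of the note in the cluster) /
#                (number of molecules in the cluster)
# An occurrence is one molecule carrying the note (note sets are
# deduplicated per molecule), so %ON sums to 100 over clusters for every
# note present in the data.

#' Per-cluster odor-note profiles
#'
#' Computes, for every (note, non-empty cluster) pair, the occurrence
#' count in the cluster, the dataset-wide count, the cluster size, and
#' the two relative statistics `pct_ON` and `pct_OM`. Zero counts are
#' reported as rows with 0, never omitted; a note absent from the whole
#' dataset gets `pct_ON = NA` (flagged, not propagated as NaN).
#'
#' @param dataset An `odor_dataset`.
#' @param assignment A `cluster_assignment` covering the dataset.
#' @param notes Notes to profile; defaults to the dataset vocabulary.
#' @return A `note_cluster_stats` tibble with columns `note`, `cluster`,
#'   `n_in_cluster`, `n_total`, `cluster_size`, `pct_ON`, `pct_OM`.
#' @export
note_profiles <- function(dataset, assignment, notes = NULL) {
  notes <- notes %||% dataset_vocabulary(dataset)
  stray <- setdiff(notes, dataset_vocabulary(dataset))
  if (length(stray) > 0) {
    warn(paste0("Note(s) outside the dataset vocabulary: ",
                paste(stray, collapse = ", ")))
  }
  pos <- match(dataset$id, assignment$id)
  if (anyNA(pos)) {
    abort("The assignment does not cover every dataset molecule.",
          class = "odorspace_config_error")
  }
  cl <- assignment$cluster[pos]
  pruned <- lapply(dataset$notes, intersect, y = notes)

  long <- tibble::tibble(
    note = unlist(pruned, use.names = FALSE),
    cluster = rep(cl, lengths(pruned))
  )
  clusters <- sort(unique(cl))
  cluster_sizes <- tibble::tibble(
    cluster = clusters,
    cluster_size = as.integer(table(factor(cl, levels = clusters)))
  )
  grid <- tidyr::expand_grid(note = sort(notes), cluster = clusters)
  counts <- dplyr::count(long, .data$note, .data$cluster, name = "n_in_cluster")
  out <- dplyr::left_join(grid, counts, by = c("note", "cluster"))
  out$n_in_cluster <- tidyr::replace_na(out$n_in_cluster, 0L)
  totals <- dplyr::summarise(dplyr::group_by(out, .data$note),
                             n_total = sum(.data$n_in_cluster),
                             .groups = "drop")
  out <- dplyr::left_join(out, totals, by = "note")
  out <- dplyr::left_join(out, cluster_sizes, by = "cluster")
  out$pct_ON <- ifelse(out$n_total > 0,
                       100 * out$n_in_cluster / out$n_total, NA_real_)
  out$pct_OM <- 100 * out$n_in_cluster / out$cluster_size
  if (any(is.na(out$pct_ON))) {
    warn(paste0("Note(s) with zero dataset occurrences (pct_ON undefined): ",
                paste(unique(out$note[is.na(out$pct_ON)]), collapse = ", ")))
  }
  tibble::new_tibble(out, class = "note_cluster_stats")
}

#' Note co-occurrence matrices
#'
#' Builds the symmetric pair-count matrix (entry ij = number of
#' molecules carrying both note i and note j; diagonal = occurrence
#' count of i) and the row-normalised nonsymmetric relative matrix
#' (entry ij = 100 * counts\[i,j\] / counts\[i,i\]): the percentage of
#' note i's occurrences that co-occur with note j. A pair is counted
#' once per molecule regardless of note order.
#'
#' @param dataset An `odor_dataset`.
#' @param notes Notes spanning the matrices (non-empty); defaults to the
#'   dataset vocabulary.
#' @param restrict_to Optional cluster index: use only that cluster's
#'   molecules for both counts and normalisation.
#' @param assignment Required when `restrict_to` is given.
#' @return A `cooc_matrices` list: `notes`, `counts`, `relative`. Rows
#'   of `relative` for notes with zero occurrences in the restriction
#'   are `NA` (flagged undefined).
#' @export
cooccurrence <- function(dataset, notes = NULL, restrict_to = NULL,
                         assignment = NULL) {
  notes <- sort(notes %||% dataset_vocabulary(dataset))
  if (length(notes) == 0) {
    abort("The note set must be non-empty.", class = "odorspace_parameter_error")
  }
  records <- dataset
  if (!is.null(restrict_to)) {
    if (is.null(assignment)) {
      abort("restrict_to requires an assignment.",
            class = "odorspace_parameter_error")
    }
    keep_ids <- assignment$id[assignment$cluster == restrict_to]
    records <- dataset[dataset$id %in% keep_ids, , drop = FALSE]
  }
  inc <- vapply(records$notes, function(nn) as.integer(notes %in% nn),
                integer(length(notes)))
  inc <- if (is.matrix(inc)) t(inc) else matrix(inc, nrow = nrow(records),
                                                byrow = TRUE)
  counts <- crossprod(inc)
  dimnames(counts) <- list(notes, notes)
  occ <- diag(counts)
  relative <- 100 * counts / occ  # rows scaled by the row note's count
  relative[occ == 0, ] <- NA_real_
  if (any(occ == 0)) {
    warn(paste0("Note(s) with zero occurrences in the restriction: ",
                paste(notes[occ == 0], collapse = ", ")))
  }
  structure(list(notes = notes, counts = counts, relative = relative,
                 restrict_to = restrict_to),
            class = "cooc_matrices")
}

#' @export
print.cooc_matrices <- function(x, ...) {
  cat("<cooc_matrices> ", length(x$notes), " notes",
      if (!is.null(x$restrict_to)) paste0(" (cluster ", x$restrict_to, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Most frequent odor notes
#'
#' @param dataset An `odor_dataset`.
#' @param k Number of notes (<= vocabulary size).
#' @param vocabulary Candidate notes (default: dataset vocabulary).
#' @return Character vector of the `k` most frequent notes, by
#'   descending occurrence count with alphabetical tie-break.
#' @export
top_frequent_notes <- function(dataset, k = 25L,
                               vocabulary = dataset_vocabulary(dataset)) {
  counts <- note_occurrences(dataset)
  counts <- counts[counts$note %in% vocabulary, , drop = FALSE]
  if (k > nrow(counts)) {
    abort(paste0("k = ", k, " exceeds the vocabulary size ", nrow(counts), "."),
          class = "odorspace_parameter_error")
  }
  counts$note[seq_len(k)]  # note_occurrences already sorts n desc, note asc
}

#' Export radar-ready profile tables
#'
#' Writes a wide note x cluster CSV of `pct_ON` (or `pct_OM`) values
#' rounded to one decimal place, the layout radar charts are drawn from.
#'
#' @param stats A `note_cluster_stats` tibble.
#' @param path Output CSV path.
#' @param value `"pct_ON"` or `"pct_OM"`.
#' @return `path`, invisibly.
#' @export
export_profile_tables <- function(stats, path, value = c("pct_ON", "pct_OM")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(stats[c("note", "cluster", value)],
                  dplyr::across(dplyr::all_of(value), ~ round(.x, 1))),
    names_from = "cluster", values_from = dplyr::all_of(value),
    names_prefix = "cluster_"
  )
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Export a co-occurrence heatmap table
#'
#' Writes the relative (nonsymmetric) co-occurrence matrix as a CSV with
#' a leading `note` column, percentages rounded to one decimal place.
#'
#' @param cooc A `cooc_matrices` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_heatmap_tables <- function(cooc, path) {
  df <- tibble::as_tibble(round(cooc$relative, 1), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(note = cooc$notes), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
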