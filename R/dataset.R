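# Odorant dataset container and vocabulary handling.
#
# An odorant dataset is a tibble with one row per molecule:
#   id     opaque identifier (character, unique)
#   name   trivial name
#   cas    CAS registry number (may be NA)
#   smiles canonical SMILES
#   notes  list-column of lowercase odor-note character vectors
# plus the attributes `vocabulary` (retained notes) and
# `min_note_occurrence` (the pruning threshold the vocabulary was built
# with). The class is `odor_dataset`, a thin tibble subclass.

new_odor_dataset <- function(records, vocabulary, min_note_occurrence) {
  stopifnot(is.data.frame(records))
  out <- tibble::new_tibble(records, class = "odor_dataset")
  attr(out, "vocabulary") <- sort(unique(vocabulary))
  attr(out, "min_note_occurrence") <- as.integer(min_note_occurrence)
  out
}

#' Construct an odorant dataset from a records table
#'
#' Validates records (unique ids, parsable SMILES, non-empty note sets),
#' canonicalises SMILES, and builds the retained-note vocabulary: the set
#' of notes carried by at least `min_note_occurrence` molecules.
#'
#' @param records Data frame with columns `id`, `name`, `smiles`, `notes`
#'   (list-column of character vectors or a `;`-delimited character
#'   column) and optionally `cas` and `family`.
#' @param min_note_occurrence Minimum number of molecules that must carry
#'   a note for it to enter the vocabulary (default 5).
#' @param external_counts Optional named integer vector of note occurrence
#'   counts from a larger source database. When supplied, vocabulary
#'   membership is decided on these counts instead of counts observed in
#'   `records` — used when a small excerpt is analysed against the
#'   statistics of its parent database.
#' @param canonicalise Canonicalise SMILES on construction (default TRUE).
#' @return An `odor_dataset` tibble. Rows whose SMILES do not parse are
#'   dropped with a warning naming them; they are never silently lost.
#' @export
odor_dataset <- function(records, min_note_occurrence = 5L,
                         external_counts = NULL, canonicalise = TRUE) {
  required <- c("id", "name", "smiles", "notes")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "odorspace_config_error")
  }
  if (nrow(records) == 0) {
    abort("The odorant table contains no records.",
          class = "odorspace_empty_dataset")
  }
  records <- tibble::as_tibble(records)
  if (!"cas" %in% names(records)) records$cas <- NA_character_
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id)) {
    abort("Duplicate record ids in the odorant table.",
          class = "odorspace_config_error")
  }

  if (!is.list(records$notes)) {
    records$notes <- lapply(records$notes, parse_notes)
  } else {
    records$notes <- lapply(records$notes, function(n) unique(normalize_notes(n)))
  }

  if (canonicalise) {
    can <- canonical_smiles(records$smiles)
  } else {
    can <- records$smiles
  }
  bad <- is.na(can)
  if (any(bad)) {
    warn(paste0("Skipping ", sum(bad), " record(s) with unparsable SMILES: ",
                paste(records$id[bad], collapse = ", ")))
  }
  records$smiles <- can
  skipped <- records[bad, , drop = FALSE]
  records <- records[!bad, , drop = FALSE]
  if (nrow(records) == 0) {
    abort("No records left after removing unparsable SMILES.",
          class = "odorspace_empty_dataset")
  }

  empty_notes <- lengths(records$notes) == 0
  if (any(empty_notes)) {
    abort(paste0("Record(s) with empty note sets: ",
                 paste(records$id[empty_notes], collapse = ", ")),
          class = "odorspace_config_error")
  }

  vocab <- build_vocabulary(records, min_occurrence = min_note_occurrence,
                            external_counts = external_counts)
  out <- new_odor_dataset(records, vocab, min_note_occurrence)
  attr(out, "skipped") <- skipped
  out
}

#' Read an odorant table from CSV
#'
#' Expects a header row naming at least the `id`, `name`, `smiles` and
#' `notes` columns (`cas` optional); notes are delimiter-separated inside
#' one column, lowercased, whitespace-normalised and deduplicated on
#' load. Rows with unparsable SMILES are reported and skipped.
#'
#' @param path CSV file path.
#' @param note_delimiter Separator between notes inside the notes column.
#' @inheritParams odor_dataset
#' @return An `odor_dataset`.
#' @export
read_odorant_table <- function(path, note_delimiter = ";",
                               min_note_occurrence = 5L,
                               external_counts = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "odorspace_config_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    abort("The odorant table contains no records.",
          class = "odorspace_empty_dataset")
  }
  df$notes <- lapply(df$notes, parse_notes, delimiter = note_delimiter)
  odor_dataset(df, min_note_occurrence = min_note_occurrence,
               external_counts = external_counts)
}

#' Write an odorant dataset back to CSV
#'
#' Inverse of [read_odorant_table()]: notes are joined with `"; "` so a
#' write/read round trip reproduces identical records.
#'
#' @param x An `odor_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_odorant_table <- function(x, path) {
  df <- tibble::as_tibble(x)
  df$notes <- vapply(df$notes, paste, character(1), collapse = "; ")
  cols <- intersect(c("id", "name", "cas", "smiles", "notes", "family"), names(df))
  readr::write_csv(df[cols], path, progress = FALSE)
  invisible(path)
}

#' @export
print.odor_dataset <- function(x, ...) {
  cat("<odor_dataset> ", nrow(x), " molecules, ",
      length(attr(x, "vocabulary")), " vocabulary notes (min occurrence ",
      attr(x, "min_note_occurrence"), ")\n", sep = "")
  NextMethod()
}

#' Retained-note vocabulary of a dataset
#' @param x An `odor_dataset`.
#' @return Character vector of retained notes, sorted.
#' @export
dataset_vocabulary <- function(x) {
  v <- attr(x, "vocabulary")
  if (is.null(v)) v <- build_vocabulary(x, attr(x, "min_note_occurrence") %||% 5L)
  v
}

#' Occurrence count of every note in a dataset
#'
#' One occurrence is one molecule carrying the note (notes are
#' deduplicated within a record, so a note counts at most once per
#' molecule).
#'
#' @param x An `odor_dataset` or a records data frame with a `notes`
#'   list-column.
#' @return Tibble with columns `note` and `n`, sorted by decreasing `n`
#'   and then alphabetically.
#' @export
note_occurrences <- function(x) {
  notes <- unlist(x$notes, use.names = FALSE)
  if (length(notes) == 0) return(tibble::tibble(note = character(), n = integer()))
  tab <- table(notes)
  out <- tibble::tibble(note = names(tab), n = as.integer(tab))
  dplyr::arrange(out, dplyr::desc(.data$n), .data$note)
}

#' Build the retained-note vocabulary
#'
#' Returns exactly the notes carried by at least `min_occurrence` records
#' (or, when `external_counts` is given, the notes whose external count
#' meets the threshold).
#'
#' @param records An `odor_dataset` or records data frame with a `notes`
#'   list-column.
#' @param min_occurrence Occurrence threshold (>= 1).
#' @param external_counts Optional named integer vector of occurrence
#'   counts from a parent database; notes absent from it fall back to the
#'   observed count.
#' @return Character vector of retained notes, sorted.
#' @export
build_vocabulary <- function(records, min_occurrence = 5L,
                             external_counts = NULL) {
  stopifnot(min_occurrence >= 1L)
  counts <- note_occurrences(records)
  n <- counts$n
  if (!is.null(external_counts)) {
    ext <- external_counts[counts$note]
    n <- ifelse(is.na(ext), n, ext)
  }
  sort(counts$note[n >= min_occurrence])
}

#' Pruned view of a record's note set
#'
#' Intersects every record's notes with the vocabulary. Records that lose
#' all their notes are reported with a warning (never silently emptied).
#'
#' @param x An `odor_dataset`.
#' @param vocabulary Defaults to the dataset vocabulary.
#' @return `x` with pruned note sets (vocabulary attribute preserved).
#' @export
prune_notes <- function(x, vocabulary = dataset_vocabulary(x)) {
  pruned <- lapply(x$notes, intersect, y = vocabulary)
  emptied <- lengths(pruned) == 0 & lengths(x$notes) > 0
  if (any(emptied)) {
    warn(paste0("Pruning emptied the note sets of: ",
                paste(x$id[emptied], collapse = ", ")))
  }
  x$notes <- pruned
  x
}

#' Notes two odorants have in common
#'
#' Set intersection of the two records' note sets; symmetric in the two
#' ids.
#'
#' @param dataset An `odor_dataset`.
#' @param a,b Record ids.
#' @param pruned Intersect against the vocabulary first (default TRUE).
#' @return Sorted character vector of shared notes.
#' @export
common_notes <- function(dataset, a, b, pruned = TRUE) {
  na <- record_notes(dataset, a, pruned = pruned)
  nb <- record_notes(dataset, b, pruned = pruned)
  sort(intersect(na, nb))
}

record_notes <- function(dataset, id, pruned = TRUE) {
  i <- match(id, dataset$id)
  if (is.na(i)) {
    abort(paste0("Unknown record id: ", id), class = "odorspace_lookup_error")
  }
  n <- dataset$notes[[i]]
  if (pruned) n <- intersect(n, dataset_vocabulary(dataset))
  n
}

#' Define a mixture fixture
#'
#' A named odorant mixture: component record ids and, optionally, their
#' percentage proportions (which must total 100 within 0.5).
#'
#' @param name Mixture name.
#' @param components Character vector of record ids.
#' @param proportions Optional numeric percentages, one per component.
#' @return A `mixture_fixture` list.
#' @export
mixture_fixture <- function(name, components, proportions = NULL) {
  stopifnot(is_string(name), is.character(components), length(components) > 0)
  if (!is.null(proportions)) {
    stopifnot(length(proportions) == length(components))
    if (abs(sum(proportions) - 100) > 0.5) {
      abort(paste0("Mixture proportions sum to ", sum(proportions),
                   ", expected 100 +/- 0.5."),
            class = "odorspace_config_error")
    }
  }
  structure(list(name = name, components = components,
                 proportions = proportions),
            class = "mixture_fixture")
}

#' @export
print.mixture_fixture <- function(x, ...) {
  cat("<mixture_fixture> ", x$name, ": ",
      paste(x$components, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Union of the pruned note sets of a mixture's components
#'
#' @param mixture A `mixture_fixture` (or a character vector of record
#'   ids, treated as an anonymous mixture).
#' @param dataset An `odor_dataset` resolving the component ids.
#' @return Sorted character vector of notes.
#' @export
mixture_note_union <- function(mixture, dataset) {
  ids <- if (inherits(mixture, "mixture_fixture")) mixture$components else mixture
  notes <- lapply(ids, function(id) record_notes(dataset, id, pruned = TRUE))
  sort(unique(unlist(notes)))
}
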