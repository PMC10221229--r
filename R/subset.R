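# Rule-based selection of cluster members whose odor profile resembles a
# reference odorant.
#
# For each candidate the four profile-similarity descriptors are
# computed: the number of notes shared with the reference, the number of
# candidate notes absent from the reference ("noncommon", counted on the
# candidate side), and the two percentages. The hard rule keeps
# candidates with at least `min_common` shared notes and at most
# `max_noncommon` foreign ones; over-full selections are refined by
# smallest percentage of noncommon notes, then largest percentage of
# common notes, then candidate id, and truncated at the cap.

#' Odor-profile similarity between a reference and a candidate
#'
#' @param dataset An `odor_dataset`.
#' @param reference,candidate Record ids.
#' @param convention Denominator convention: `"candidate"` (default)
#'   normalises `pct_common` by the reference note count and
#'   `pct_noncommon` by the candidate note count; `"union"` normalises
#'   both by the size of the union of the two note sets.
#' @return A `profile_similarity` tibble row: `reference_id`,
#'   `candidate_id`, `n_common`, `n_noncommon`, `pct_common`,
#'   `pct_noncommon`.
#' @export
profile_similarity <- function(dataset, reference, candidate,
                               convention = c("candidate", "union")) {
  convention <- match.arg(convention)
  ref <- record_notes(dataset, reference, pruned = TRUE)
  cand <- record_notes(dataset, candidate, pruned = TRUE)
  if (length(ref) == 0 || length(cand) == 0) {
    abort("Profile similarity is undefined for an empty pruned note set.",
          class = "odorspace_similarity_error")
  }
  similarity_row(reference, candidate, ref, cand, convention)
}

similarity_row <- function(ref_id, cand_id, ref, cand, convention) {
  n_common <- length(intersect(cand, ref))
  n_noncommon <- length(setdiff(cand, ref))
  if (convention == "candidate") {
    pct_common <- 100 * n_common / length(ref)
    pct_noncommon <- 100 * n_noncommon / length(cand)
  } else {
    u <- length(union(ref, cand))
    pct_common <- 100 * n_common / u
    pct_noncommon <- 100 * n_noncommon / u
  }
  tibble::new_tibble(
    tibble::tibble(reference_id = ref_id, candidate_id = cand_id,
                   n_common = n_common, n_noncommon = n_noncommon,
                   pct_common = pct_common, pct_noncommon = pct_noncommon),
    class = "profile_similarity"
  )
}

#' Select cluster members with an odor profile close to a reference
#'
#' Stage 1 keeps candidates with `n_common >= min_common` and
#' `n_noncommon <= max_noncommon`. If more than `cap` survive, stage 2
#' prefers the smallest percentage of noncommon notes and stage 3 the
#' largest percentage of common notes; remaining ties break on candidate
#' id, and the list is truncated at `cap`. The reference is excluded
#' from the candidate pool but listed first in the resulting subset, so
#' a subset of size s contains the reference plus s - 1 selected
#' molecules. Fully deterministic.
#'
#' @param dataset An `odor_dataset`.
#' @param reference Reference record id.
#' @param members Candidate record ids. Alternatively pass `assignment`
#'   and `cluster` to use a cluster's members.
#' @param assignment Optional `cluster_assignment`.
#' @param cluster Optional cluster index within `assignment`.
#' @param cap Maximum number of selected candidates (default 10).
#' @param min_common Minimum shared notes (default 3).
#' @param max_noncommon Maximum candidate-side foreign notes (default 2).
#' @inheritParams profile_similarity
#' @return A `subset_result` list: `reference_id`, `cluster`,
#'   `selected_ids` (reference first), and `audit` — one row per
#'   candidate with its descriptors, pass/fail flag and reason.
#' @export
select_subset <- function(dataset, reference, members = NULL,
                          assignment = NULL, cluster = NULL, cap = 10L,
                          min_common = 3L, max_noncommon = 2L,
                          convention = c("candidate", "union")) {
  convention <- match.arg(convention)
  if (is.null(members)) {
    if (is.null(assignment) || is.null(cluster)) {
      abort("Provide either members or assignment + cluster.",
            class = "odorspace_parameter_error")
    }
    members <- assignment$id[assignment$cluster == cluster]
  }
  members <- setdiff(members, reference)
  ref_notes <- record_notes(dataset, reference, pruned = TRUE)
  if (length(ref_notes) == 0) {
    abort("The reference has an empty pruned note set.",
          class = "odorspace_similarity_error")
  }

  audit <- purrr::map_dfr(members, function(m) {
    cand <- record_notes(dataset, m, pruned = TRUE)
    if (length(cand) == 0) {
      return(tibble::tibble(reference_id = reference, candidate_id = m,
                            n_common = NA_integer_, n_noncommon = NA_integer_,
                            pct_common = NA_real_, pct_noncommon = NA_real_))
    }
    similarity_row(reference, m, ref_notes, cand, convention)
  })
  audit$pass_hard_rule <- !is.na(audit$n_common) &
    audit$n_common >= min_common & audit$n_noncommon <= max_noncommon
  audit$reason <- dplyr::case_when(
    is.na(audit$n_common) ~ "empty pruned note set",
    audit$n_common < min_common ~ sprintf("fewer than %d common notes", min_common),
    audit$n_noncommon > max_noncommon ~ sprintf("more than %d noncommon notes", max_noncommon),
    TRUE ~ "passed hard rule"
  )

  survivors <- audit[audit$pass_hard_rule, , drop = FALSE]
  survivors <- dplyr::arrange(survivors, .data$pct_noncommon,
                              dplyr::desc(.data$pct_common),
                              .data$candidate_id)
  selected <- utils::head(survivors$candidate_id, cap)
  audit$selected <- audit$candidate_id %in% selected
  audit$reason[audit$pass_hard_rule & !audit$selected] <-
    "passed hard rule, beyond cap after refinement"

  structure(list(reference_id = reference, cluster = cluster,
                 selected_ids = c(reference, selected), audit = audit,
                 cap = cap, min_common = min_common,
                 max_noncommon = max_noncommon, convention = convention),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat("<subset_result> reference ", x$reference_id,
      if (!is.null(x$cluster)) paste0(" (cluster ", x$cluster, ")"),
      ": ", length(x$selected_ids) - 1L, " selected of ",
      nrow(x$audit), " candidates\n", sep = "")
  invisible(x)
}
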