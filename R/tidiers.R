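# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pharmacophore hypothesis
#'
#' @param x A `pharmacophore_hypothesis`.
#' @param ... Ignored.
#' @return Tibble of the hypothesis features: `label`, `kind`, `x`,
#'   `y`, `z`.
#' @export
tidy.pharmacophore_hypothesis <- function(x, ...) {
  hid <- x$id
  dplyr::mutate(x$features[c("label", "kind", "x", "y", "z")],
                hypothesis = hid, .before = 1)
}

#' One-row summary of a pharmacophore hypothesis
#'
#' @param x A `pharmacophore_hypothesis`.
#' @param ... Ignored.
#' @return Tibble with `hypothesis`, `signature`, `n_features`,
#'   `n_matched`, `n_units`, `matched_fraction`, `mean_rmsd`, `score`.
#' @export
glance.pharmacophore_hypothesis <- function(x, ...) {
  tibble::tibble(
    hypothesis = x$id, signature = x$signature,
    n_features = nrow(x$features), n_matched = nrow(x$matched),
    n_units = x$n_units, matched_fraction = nrow(x$matched) / x$n_units,
    mean_rmsd = mean(x$matched$rmsd), score = x$score
  )
}

#' Summaries of a ranked hypothesis set
#'
#' @param x A `hypothesis_set`.
#' @param ... Ignored.
#' @return One [glance.pharmacophore_hypothesis()] row per hypothesis.
#' @export
glance.hypothesis_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}

#' @rdname glance.hypothesis_set
#' @export
tidy.hypothesis_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' Tidy a cluster-selection report
#'
#' @param x A `cluster_selection`.
#' @param ... Ignored.
#' @return The per-k report tibble.
#' @export
tidy.cluster_selection <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a cluster-selection report
#'
#' @param x A `cluster_selection`.
#' @param ... Ignored.
#' @return Tibble with `k_optimal`, `k_min`, `k_max`, `min_penalty`.
#' @export
glance.cluster_selection <- function(x, ...) {
  kr <- attr(x, "k_range")
  tibble::tibble(k_optimal = attr(x, "k_optimal"),
                 k_min = min(kr), k_max = max(kr),
                 min_penalty = min(x$penalty, na.rm = TRUE))
}

#' Tidy a hypothesis alignment
#'
#' @param x A `hypothesis_alignment`.
#' @param ... Ignored.
#' @return One-row tibble: `reference_id`, `other_id`, `success`,
#'   `rmsd`, `n_paired`.
#' @export
tidy.hypothesis_alignment <- function(x, ...) {
  tibble::tibble(reference_id = x$reference_id, other_id = x$other_id,
                 success = x$success, rmsd = x$rmsd,
                 n_paired = if (is.null(x$feature_mapping)) 0L
                            else nrow(x$feature_mapping))
}

#' Tidy a subset-selection result
#'
#' @param x A `subset_result`.
#' @param ... Ignored.
#' @return The per-candidate audit tibble.
#' @export
tidy.subset_result <- function(x, ...) {
  x$audit
}

#' One-row summary of a subset-selection result
#'
#' @param x A `subset_result`.
#' @param ... Ignored.
#' @return Tibble with `reference_id`, `cluster`, `n_candidates`,
#'   `n_pass_hard_rule`, `n_selected`, `subset_size`.
#' @export
glance.subset_result <- function(x, ...) {
  tibble::tibble(reference_id = x$reference_id,
                 cluster = x$cluster %||% NA_integer_,
                 n_candidates = nrow(x$audit),
                 n_pass_hard_rule = sum(x$audit$pass_hard_rule, na.rm = TRUE),
                 n_selected = sum(x$audit$selected),
                 subset_size = length(x$selected_ids))
}
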