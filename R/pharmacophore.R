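# Common-feature pharmacophore elucidation.
#
# A hypothesis is a rigid arrangement of at least `min_features` typed
# feature points (A/H/R) that a required fraction of the input
# molecules can realise with some conformer to within a spatial
# tolerance. The search enumerates feature subsets per conformer, keys
# them by kind signature and binned interfeature distances (1 Angstrom
# bins with adjacent-bin matching operationalise the 2 Angstrom
# tolerance for candidate grouping — a pruning heuristic, not the
# decision rule), and accepts molecules whose best-matching subset
# superposes onto the reference arrangement with feature RMSD at most
# the tolerance. Scoring is transparent:
#   score = 0.4 * matched fraction
#         + 0.4 * (1 - mean feature RMSD / tolerance)
#         + 0.2 * (n_features - min_features + 1) / 4
# rewarding coverage, geometric tightness and feature richness.
#
# With a single molecule as input, the molecule's conformers play the
# role of the molecules: the result is the pharmacophore of its own
# conformational space.

new_hypothesis <- function(id, signature, features, tolerance, matched,
                           score, n_units, reference, params) {
  dm <- as.matrix(stats::dist(features[, c("x", "y", "z")]))
  dimnames(dm) <- list(features$label, features$label)
  structure(list(id = id, signature = signature, features = features,
                 tolerance = tolerance, matched = matched, score = score,
                 n_units = n_units, distance_matrix = dm,
                 reference = reference, params = params),
            class = "pharmacophore_hypothesis")
}

#' @export
print.pharmacophore_hypothesis <- function(x, ...) {
  cat("<pharmacophore_hypothesis> ", x$id, " (", x$signature, "): score ",
      round(x$score, 3), ", ", nrow(x$matched), "/", x$n_units,
      " matched, tolerance ", x$tolerance, " A\n", sep = "")
  invisible(x)
}

# Relabel a feature subset in the canonical order: acceptors first,
# then hydrophobes, then rings, numbered across the whole set.
relabel_features <- function(features) {
  kind_rank <- c(A = 1L, H = 2L, R = 3L)
  features <- features[order(kind_rank[features$kind]), , drop = FALSE]
  features$label <- paste0(features$kind, seq_len(nrow(features)))
  features
}

# All feature subsets of one unit, grouped by kind signature. For each
# signature: the conformer index, subset (feature indices) and binned
# sorted interfeature distance vector of every candidate.
unit_candidates <- function(kinds, positions, min_features, max_features) {
  nfeat <- length(kinds)
  if (nfeat < min_features) return(list())
  groups <- list()
  for (s in seq(min_features, min(max_features, nfeat))) {
    subsets <- utils::combn(nfeat, s, simplify = FALSE)
    for (sub in subsets) {
      sig <- paste(sort(kinds[sub]), collapse = "")
      for (ci in seq_along(positions)) {
        dvec <- sort(stats::dist(positions[[ci]][sub, , drop = FALSE]))
        g <- groups[[sig]]
        if (is.null(g)) g <- list(conformer = integer(), subset = list(),
                                  bins = list())
        k <- length(g$conformer) + 1L
        g$conformer[k] <- ci
        g$subset[[k]] <- sub
        g$bins[[k]] <- as.integer(round(dvec))
        groups[[sig]] <- g
      }
    }
  }
  lapply(groups, function(g) {
    g$binmat <- do.call(rbind, g$bins)
    g
  })
}

# Indices of candidates in group `g` whose binned distance vector is
# elementwise within one bin of `bins`.
adjacent_candidates <- function(g, bins) {
  if (is.null(g) || ncol(g$binmat) != length(bins)) return(integer())
  dev <- abs(sweep(g$binmat, 2, bins))
  which(apply(dev, 1, max) <= 1L)
}

#' Find common-feature pharmacophore hypotheses
#'
#' Searches the conformer ensembles for arrangements of
#' `min_features`..`max_features` typed features shared by at least
#' `match_fraction` of the molecules within `tolerance`, and returns up
#' to `max_hypotheses` hypotheses ranked by score (ties: more features,
#' then lexicographic signature). With a single ensemble the search
#' runs over that molecule's conformers (single-molecule mode). An
#' empty result (length 0, with a message) is valid: nothing survived.
#'
#' @param ensembles A `conformer_set`, list of `conformer_ensemble`s,
#'   or one `conformer_ensemble`.
#' @param min_features Minimum features per hypothesis (default 3).
#' @param tolerance Feature-matching tolerance in Angstrom (default 2).
#' @param match_fraction Minimum fraction of molecules that must match
#'   (default 0.5).
#' @param max_hypotheses Maximum number of returned hypotheses
#'   (default 10).
#' @param max_features Subset-size cap (default 6).
#' @param aromatic_as_hydrophobic Re-type R features as H during
#'   perception.
#' @param rules Feature perception rules.
#' @return A `hypothesis_set`: list of `pharmacophore_hypothesis`
#'   objects, best first.
#' @export
find_common_pharmacophores <- function(ensembles, min_features = 3L,
                                       tolerance = 2, match_fraction = 0.5,
                                       max_hypotheses = 10L,
                                       max_features = 6L,
                                       aromatic_as_hydrophobic = FALSE,
                                       rules = feature_rules()) {
  if (inherits(ensembles, "conformer_ensemble")) ensembles <- list(ensembles)
  ensembles <- unclass(ensembles)
  if (length(ensembles) == 0) {
    abort("At least one conformer ensemble is required.",
          class = "odorspace_parameter_error")
  }
  stopifnot(min_features >= 3, tolerance > 0,
            match_fraction > 0, match_fraction <= 1)

  single <- length(ensembles) == 1L
  units <- list()
  for (e in ensembles) {
    src <- perceive_sources(molecule_3d(e, 1L), aromatic_as_hydrophobic, rules)
    kinds <- vapply(src, `[[`, character(1), "kind")
    positions <- purrr::map(e$coords, function(cc) feature_positions(src, cc))
    template <- perceive_features(molecule_3d(e, 1L),
                                  aromatic_as_hydrophobic, rules)
    if (single) {
      for (ci in seq_along(positions)) {
        units[[length(units) + 1L]] <- list(
          id = e$molecule_id, conformer = ci, kinds = kinds,
          positions = positions[ci], template = template, n_conformers = 1L)
      }
    } else {
      units[[length(units) + 1L]] <- list(
        id = e$molecule_id, conformer = NA_integer_, kinds = kinds,
        positions = positions, template = template,
        n_conformers = length(positions))
    }
  }
  search_common_hypotheses(units, min_features = min_features,
                           tolerance = tolerance,
                           match_fraction = match_fraction,
                           max_hypotheses = max_hypotheses,
                           max_features = max_features, single = single)
}

# Core search over prepared units. A unit is a list with fields `id`,
# `conformer` (NA outside single-molecule mode), `kinds`, `positions`
# (list of feature-coordinate matrices, one per usable conformer),
# `template` (feature tibble) and `n_conformers`. Split out from
# find_common_pharmacophores so the search can be exercised on
# synthetic feature geometries directly.
search_common_hypotheses <- function(units, min_features = 3L, tolerance = 2,
                                     match_fraction = 0.5,
                                     max_hypotheses = 10L, max_features = 6L,
                                     single = FALSE) {
  n_units <- length(units)
  need <- ceiling(match_fraction * n_units)

  cands <- purrr::map(units, function(u) {
    unit_candidates(u$kinds, u$positions, min_features, max_features)
  })

  # distinct candidate keys, in deterministic unit/candidate order
  keys <- list()
  for (ui in seq_len(n_units)) {
    for (sig in names(cands[[ui]])) {
      g <- cands[[ui]][[sig]]
      for (k in seq_along(g$conformer)) {
        key <- paste0(sig, "|", paste(g$bins[[k]], collapse = ","))
        if (is.null(keys[[key]])) {
          keys[[key]] <- list(signature = sig, bins = g$bins[[k]])
        }
      }
    }
  }

  hypotheses <- list()
  seen_refs <- character()
  for (key in names(keys)) {
    sig <- keys[[key]]$signature
    bins <- keys[[key]]$bins
    hits <- lapply(seq_len(n_units),
                   function(ui) adjacent_candidates(cands[[ui]][[sig]], bins))
    matching_units <- which(lengths(hits) > 0)
    if (length(matching_units) < need) next

    # reference: matching unit with the fewest conformers, then order;
    # its lowest-energy-conformer, first-subset matching candidate
    nconf <- vapply(matching_units, function(ui) units[[ui]]$n_conformers,
                    integer(1))
    ref_ui <- matching_units[order(nconf, matching_units)][1]
    g_ref <- cands[[ref_ui]][[sig]]
    ref_k <- hits[[ref_ui]][order(g_ref$conformer[hits[[ref_ui]]])][1]

    ref_key <- paste0(units[[ref_ui]]$id, "#", units[[ref_ui]]$conformer, "#",
                      g_ref$conformer[ref_k], "#",
                      paste(g_ref$subset[[ref_k]], collapse = "-"))
    if (ref_key %in% seen_refs) next  # adjacent key, identical reference
    seen_refs <- c(seen_refs, ref_key)

    ref_unit <- units[[ref_ui]]
    ref_subset <- g_ref$subset[[ref_k]]
    ref_pos <- ref_unit$positions[[g_ref$conformer[ref_k]]][ref_subset, ,
                                                            drop = FALSE]
    ref_kinds <- ref_unit$kinds[ref_subset]
    ref_bins <- g_ref$bins[[ref_k]]
    s <- length(ref_subset)

    matched <- list()
    for (ui in seq_len(n_units)) {
      u <- units[[ui]]
      if (ui == ref_ui) {
        matched[[length(matched) + 1L]] <- tibble::tibble(
          id = u$id,
          conformer = if (single) u$conformer else g_ref$conformer[ref_k],
          rmsd = 0)
        next
      }
      g <- cands[[ui]][[sig]]
      best_rmsd <- Inf; best_conf <- NA_integer_
      for (k in adjacent_candidates(g, ref_bins)) {
        pos <- u$positions[[g$conformer[k]]][g$subset[[k]], , drop = FALSE]
        fit <- best_feature_mapping(ref_kinds, ref_pos,
                                    u$kinds[g$subset[[k]]], pos,
                                    min_size = s, max_rmsd = tolerance)
        if (!is.null(fit) && fit$rmsd < best_rmsd) {
          best_rmsd <- fit$rmsd
          best_conf <- if (single) u$conformer else g$conformer[k]
        }
      }
      if (best_rmsd <= tolerance) {
        matched[[length(matched) + 1L]] <- tibble::tibble(
          id = u$id, conformer = best_conf, rmsd = best_rmsd)
      }
    }
    matched <- dplyr::bind_rows(matched)
    frac <- nrow(matched) / n_units
    if (frac < match_fraction) next

    features <- ref_unit$template[ref_subset, , drop = FALSE]
    features[, c("x", "y", "z")] <- ref_pos
    features <- relabel_features(features)
    score <- 0.4 * frac +
      0.4 * (1 - mean(matched$rmsd) / tolerance) +
      0.2 * (s - min_features + 1) / 4
    hypotheses[[length(hypotheses) + 1L]] <- new_hypothesis(
      id = NA_character_, signature = sig, features = features,
      tolerance = tolerance, matched = matched, score = score,
      n_units = n_units,
      reference = list(id = ref_unit$id,
                       conformer = if (single) ref_unit$conformer
                                   else g_ref$conformer[ref_k]),
      params = list(min_features = min_features, max_features = max_features,
                    match_fraction = match_fraction,
                    single_molecule = single))
  }

  if (length(hypotheses) == 0) {
    inform("No common-feature hypothesis survived.")
    return(structure(list(), class = "hypothesis_set"))
  }
  score <- vapply(hypotheses, `[[`, numeric(1), "score")
  nfeat <- vapply(hypotheses, function(h) nrow(h$features), integer(1))
  sig <- vapply(hypotheses, `[[`, character(1), "signature")
  ord <- order(-score, -nfeat, sig)
  hypotheses <- hypotheses[ord][seq_len(min(max_hypotheses, length(hypotheses)))]
  counter <- integer()
  for (i in seq_along(hypotheses)) {
    s <- hypotheses[[i]]$signature
    counter[s] <- (if (s %in% names(counter)) counter[[s]] else 0L) + 1L
    hypotheses[[i]]$id <- paste0(s, "_", counter[[s]])
  }
  structure(hypotheses, class = "hypothesis_set")
}

#' @export
print.hypothesis_set <- function(x, ...) {
  cat("<hypothesis_set> ", length(x), " hypothesis(es)\n", sep = "")
  for (h in x) print(h)
  invisible(x)
}

#' Interfeature distance table of a hypothesis
#'
#' @param hypothesis A `pharmacophore_hypothesis`.
#' @return Tibble with columns `from`, `to`, `distance` (Angstrom), one
#'   row per unordered feature pair, labelled in the "A1", "H3" style.
#' @export
interfeature_distances <- function(hypothesis) {
  stopifnot(inherits(hypothesis, "pharmacophore_hypothesis"))
  dm <- hypothesis$distance_matrix
  labs <- rownames(dm)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  tibble::tibble(from = labs[idx[, 1]], to = labs[idx[, 2]],
                 distance = dm[idx])
}

#' A-A distance of the best hypothesis with two acceptors
#'
#' Convenience accessor: walks a ranked `hypothesis_set`, takes the
#' first hypothesis containing at least two acceptor features and
#' returns the distance between its first two acceptors.
#'
#' @param hypotheses A `hypothesis_set`.
#' @return Distance in Angstrom (NA if no hypothesis has two acceptors).
#' @export
acceptor_pair_distance <- function(hypotheses) {
  for (h in hypotheses) {
    a <- h$features$label[h$features$kind == "A"]
    if (length(a) >= 2) return(h$distance_matrix[a[1], a[2]])
  }
  NA_real_
}
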