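# Least-squares rigid superposition (Kabsch) and pairwise alignment of
# pharmacophore hypotheses.

#' Least-squares rigid superposition of paired points
#'
#' Finds the proper rotation and translation minimising the RMSD
#' between two paired point sets (Kabsch algorithm via SVD, with the
#' reflection guard).
#'
#' @param moving,target Matrices of paired coordinates (m x 3).
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   superposed points are `moving %*% rotation` + translation),
#'   `rmsd`, and `fitted` (the superposed moving points).
#' @export
kabsch_superpose <- function(moving, target) {
  stopifnot(nrow(moving) == nrow(target), ncol(moving) == 3, ncol(target) == 3)
  mc <- colMeans(moving); tc <- colMeans(target)
  P <- sweep(moving, 2, mc)
  Q <- sweep(target, 2, tc)
  C <- crossprod(P, Q)
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P %*% R
  fitted <- sweep(fitted, 2, tc, "+")
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  list(rotation = R, translation = tc - as.numeric(mc %*% R),
       rmsd = rmsd, fitted = fitted)
}

# Enumerate type-preserving partial bijections between two labelled
# point sets and return the minimum-RMSD pairing of size >= min_size.
# Pairs are pruned when an internal pairwise distance mismatch proves
# the pairing cannot reach `max_rmsd` (|d1 - d2| <= sqrt(2 m) rmsd for
# any rigid superposition of m points), so a NULL result with
# `prune_proof = TRUE` certifies min RMSD > max_rmsd.
best_feature_mapping <- function(kind1, pos1, kind2, pos2, min_size = 3L,
                                 max_rmsd = Inf) {
  n1 <- length(kind1); n2 <- length(kind2)
  if (min(n1, n2) < min_size) return(NULL)
  d1 <- as.matrix(stats::dist(pos1))
  d2 <- as.matrix(stats::dist(pos2))
  bound <- if (is.finite(max_rmsd)) sqrt(2 * min(n1, n2)) * max_rmsd else Inf

  best <- NULL
  recurse <- function(pairs, next_i) {
    m <- nrow(pairs)
    if (m >= min_size) {
      fit <- kabsch_superpose(pos1[pairs[, 1], , drop = FALSE],
                              pos2[pairs[, 2], , drop = FALSE])
      if (is.null(best) || fit$rmsd < best$rmsd - 1e-12 ||
          (abs(fit$rmsd - best$rmsd) <= 1e-12 && m > nrow(best$pairs))) {
        best <<- list(pairs = pairs, rmsd = fit$rmsd, fit = fit)
      }
    }
    if (next_i > n1) return()
    for (i in next_i:n1) {
      for (j in seq_len(n2)) {
        if (kind2[j] != kind1[i]) next
        if (m > 0 && j %in% pairs[, 2]) next
        ok <- TRUE
        if (m > 0) {
          for (r in seq_len(m)) {
            if (abs(d1[pairs[r, 1], i] - d2[pairs[r, 2], j]) > bound) {
              ok <- FALSE; break
            }
          }
        }
        if (!ok) next
        recurse(rbind(pairs, c(i, j)), i + 1L)
      }
    }
  }
  recurse(matrix(integer(), ncol = 2), 1L)
  best
}

#' Align two pharmacophore hypotheses
#'
#' Searches every type-preserving pairing of at least `min_size`
#' features between the two hypotheses (feature counts are small, so
#' the search is exhaustive), superposes each pairing by least-squares
#' rigid fit, and returns the minimum-RMSD pairing. The alignment is
#' declared a failure — a result with `success = FALSE` — when no
#' type-preserving pairing of the required size exists or the best RMSD
#' exceeds `rmsd_cutoff`.
#'
#' @param reference,other `pharmacophore_hypothesis` objects; the
#'   reference acts as the fixed template.
#' @param rmsd_cutoff Acceptance cutoff in Angstrom (default 2, the
#'   feature-matching tolerance).
#' @param r_as_h Allow aromatic-ring features to pair with hydrophobes
#'   (default FALSE).
#' @param min_size Minimum number of paired features (default 3).
#' @return A `hypothesis_alignment` list: `reference_id`, `other_id`,
#'   `success`, `rmsd` (NA when no pairing of the required size
#'   exists), `feature_mapping` (tibble of paired labels), `rotation`,
#'   `translation`.
#' @export
align_hypotheses <- function(reference, other, rmsd_cutoff = 2,
                             r_as_h = FALSE, min_size = 3L) {
  stopifnot(inherits(reference, "pharmacophore_hypothesis"),
            inherits(other, "pharmacophore_hypothesis"))
  k1 <- reference$features$kind
  k2 <- other$features$kind
  if (r_as_h) {
    k1[k1 == "R"] <- "H"
    k2[k2 == "R"] <- "H"
  }
  p1 <- as.matrix(reference$features[c("x", "y", "z")])
  p2 <- as.matrix(other$features[c("x", "y", "z")])
  best <- best_feature_mapping(k1, p1, k2, p2, min_size = min_size,
                               max_rmsd = rmsd_cutoff)
  if (is.null(best)) {
    out <- list(reference_id = reference$id, other_id = other$id,
                success = FALSE, rmsd = NA_real_,
                feature_mapping = NULL, rotation = NULL, translation = NULL)
    return(structure(out, class = "hypothesis_alignment"))
  }
  mapping <- tibble::tibble(
    reference_feature = reference$features$label[best$pairs[, 1]],
    other_feature = other$features$label[best$pairs[, 2]]
  )
  # superpose the *other* onto the reference template
  fit <- kabsch_superpose(p2[best$pairs[, 2], , drop = FALSE],
                          p1[best$pairs[, 1], , drop = FALSE])
  structure(list(reference_id = reference$id, other_id = other$id,
                 success = fit$rmsd <= rmsd_cutoff, rmsd = fit$rmsd,
                 feature_mapping = mapping, rotation = fit$rotation,
                 translation = fit$translation),
            class = "hypothesis_alignment")
}

#' @export
print.hypothesis_alignment <- function(x, ...) {
  cat("<hypothesis_alignment> ", x$reference_id, " vs ", x$other_id, ": ",
      if (x$success) paste0("RMSD ", signif(x$rmsd, 4), " A")
      else "no reliable alignment", "\n", sep = "")
  invisible(x)
}
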