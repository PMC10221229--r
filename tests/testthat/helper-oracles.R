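# Independent oracles: exhaustive enumeration counterparts of the
# clustering and pharmacophore searches, used to freeze expected values.

`%||%` <- function(a, b) if (is.null(a)) b else a

embedding_from_coords <- function(coords,
                                  ids = paste0("p", seq_len(nrow(coords)))) {
  colnames(coords) <- c("x", "y", "z")
  out <- tibble::new_tibble(
    dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(coords)),
    class = "odor_embedding")
  attr(out, "umap_params") <- list(dims = 3L, seed = 0L, n_neighbors = NA,
                                   min_dist = NA, metric = "euclidean")
  out
}

wss_of <- function(coords, labels) {
  sum(vapply(split(seq_len(nrow(coords)), labels), function(ix) {
    ctr <- colMeans(coords[ix, , drop = FALSE])
    sum(sweep(coords[ix, , drop = FALSE], 2, ctr)^2)
  }, numeric(1)))
}

# exhaustive minimum WSS over every assignment of n points to k labels
exhaustive_min_wss <- function(coords, k) {
  n <- nrow(coords)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    if (length(unique(labels)) == k) {
      best <- min(best, wss_of(coords, labels))
    }
    i <- n
    while (i >= 1 && labels[i] == k) { labels[i] <- 1L; i <- i - 1L }
    if (i == 0) break
    labels[i] <- labels[i] + 1L
  }
  best
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p + (p >= i), i, after = i - 1L)
    }
  }
  unique(lapply(out, as.integer))
}

# Does each unit realise the reference arrangement within the
# tolerance? Checked exactly: every conformer, subset and
# type-preserving bijection, no pruning.
oracle_matches <- function(units, ref_kinds, ref_pos, tolerance) {
  vapply(units, function(u) {
    n <- length(u$kinds)
    s <- length(ref_kinds)
    if (n < s) return(FALSE)
    for (pos in u$positions) {
      for (sub in utils::combn(n, s, simplify = FALSE)) {
        if (!identical(sort(u$kinds[sub]), sort(ref_kinds))) next
        for (p in all_permutations(s)) {
          if (!all(u$kinds[sub][p] == ref_kinds)) next
          fit <- kabsch_superpose(pos[sub, , drop = FALSE][p, , drop = FALSE],
                                  ref_pos)
          if (fit$rmsd <= tolerance) return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
}

# Signatures surviving exhaustive common-feature search, with the
# maximum matched-unit count per signature.
oracle_survivors <- function(units, min_features, tolerance, match_fraction) {
  found <- list()
  for (u in units) {
    n <- length(u$kinds)
    if (n < min_features) next
    for (pos in u$positions) {
      for (s in seq(min_features, n)) {
        for (sub in utils::combn(n, s, simplify = FALSE)) {
          ref_kinds <- u$kinds[sub]
          ref_pos <- pos[sub, , drop = FALSE]
          m <- oracle_matches(units, ref_kinds, ref_pos, tolerance)
          if (mean(m) >= match_fraction) {
            sig <- paste(sort(ref_kinds), collapse = "")
            found[[sig]] <- max(found[[sig]] %||% 0L, sum(m))
          }
        }
      }
    }
  }
  found
}
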