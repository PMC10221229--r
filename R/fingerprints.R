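# Extended-connectivity fingerprints and Tanimoto similarity.

#' Compute extended-connectivity fingerprints
#'
#' Encodes every molecule as a fixed-length binary ECFP vector. Circular
#' environments are enumerated by Open Babel up to the requested radius
#' and the raw bit space is folded down to `n_bits` by OR-ing congruent
#' positions — the standard folding scheme, so identical canonical
#' SMILES always give identical rows regardless of input atom order.
#'
#' @param x An `odor_dataset` or data frame with `id` and `smiles`
#'   columns (SMILES must be valid).
#' @param n_bits Folded fingerprint length (default 1024).
#' @param radius Circular-environment radius in bonds (default 2, the
#'   ECFP4-equivalent community default).
#' @return An `fp_matrix`: list with `ids`, `bits` (molecules x `n_bits`
#'   0/1 integer matrix) and `radius`.
#' @export
compute_fingerprints <- function(x, n_bits = 1024L, radius = 2L) {
  stopifnot(all(c("id", "smiles") %in% names(x)), n_bits >= 8, radius >= 0)
  bad <- is.na(x$smiles) | !nzchar(x$smiles)
  if (any(bad)) {
    abort(paste0("Invalid structures for record(s): ",
                 paste(x$id[bad], collapse = ", ")),
          class = "odorspace_chem_error")
  }
  raw <- obabel_fingerprints(x$id, x$smiles, paste0("ECFP", 2L * radius))
  folds <- ncol(raw) / n_bits
  if (folds != floor(folds)) {
    abort("n_bits must divide the native fingerprint length.",
          class = "odorspace_config_error")
  }
  bits <- matrix(0L, nrow = nrow(raw), ncol = n_bits)
  for (f in seq_len(folds)) {
    block <- raw[, ((f - 1L) * n_bits + 1L):(f * n_bits), drop = FALSE]
    bits <- pmax(bits, block)
  }
  rownames(bits) <- x$id
  structure(list(ids = x$id, bits = bits, radius = as.integer(radius)),
            class = "fp_matrix")
}

#' @export
print.fp_matrix <- function(x, ...) {
  cat("<fp_matrix> ", length(x$ids), " molecules x ", ncol(x$bits),
      " bits (ECFP radius ", x$radius, ")\n", sep = "")
  invisible(x)
}

#' Pairwise Tanimoto similarity of binary fingerprints
#'
#' @param fp An `fp_matrix`.
#' @return Symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @export
tanimoto_similarity <- function(fp) {
  b <- fp$bits
  common <- tcrossprod(b)
  ones <- rowSums(b)
  union <- outer(ones, ones, "+") - common
  sim <- ifelse(union == 0, 1, common / union)
  dimnames(sim) <- list(fp$ids, fp$ids)
  sim
}

#' Jaccard distance object from fingerprints
#'
#' `1 - Tanimoto`, as a `dist`, the metric used for embedding binary
#' fingerprints.
#'
#' @param fp An `fp_matrix`.
#' @return A `stats::dist` object.
#' @export
tanimoto_dist <- function(fp) {
  stats::as.dist(1 - tanimoto_similarity(fp))
}
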