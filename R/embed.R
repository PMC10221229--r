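# Three-dimensional UMAP embedding of fingerprint space.

#' Embed fingerprints into a low-dimensional chemical space
#'
#' Runs UMAP on the Jaccard (1 - Tanimoto) distances between binary
#' fingerprints (or on the raw bit vectors under the Euclidean metric)
#' and returns per-molecule coordinates. All run parameters are recorded
#' on the result; a fixed seed gives reproducible coordinates.
#'
#' @param fp An `fp_matrix`.
#' @param dims Output dimensionality (default 3).
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighbourhood size (default 15, capped at
#'   n - 1).
#' @param min_dist UMAP minimum embedded distance (default 0.1).
#' @param metric `"jaccard"` (precomputed Tanimoto distances, the
#'   default, appropriate for binary fingerprints) or `"euclidean"`.
#' @return An `odor_embedding`: tibble with columns `id` and the
#'   coordinate columns `x`, `y`, `z` (or `dim1..dimk`), with the run
#'   parameters in the `umap_params` attribute.
#' @export
embed_umap <- function(fp, dims = 3L, seed = 42L, n_neighbors = 15L,
                       min_dist = 0.1, metric = c("jaccard", "euclidean")) {
  metric <- match.arg(metric)
  n <- length(fp$ids)
  if (n < dims + 2L) {
    abort(paste0("Need at least ", dims + 2L, " molecules to embed into ",
                 dims, " dimensions; got ", n, "."),
          class = "odorspace_dimension_error")
  }
  n_neighbors <- min(n_neighbors, n - 1L)
  set.seed(seed)
  if (metric == "jaccard") {
    coords <- uwot::umap(tanimoto_dist(fp), n_components = dims,
                         n_neighbors = n_neighbors, min_dist = min_dist,
                         n_threads = 1, n_sgd_threads = 0)
  } else {
    coords <- uwot::umap(fp$bits, n_components = dims,
                         n_neighbors = n_neighbors, min_dist = min_dist,
                         metric = "euclidean",
                         n_threads = 1, n_sgd_threads = 0)
  }
  if (any(!is.finite(coords))) {
    abort("UMAP produced non-finite coordinates.",
          class = "odorspace_embed_error")
  }
  cn <- if (dims == 3L) c("x", "y", "z") else paste0("dim", seq_len(dims))
  colnames(coords) <- cn
  out <- tibble::new_tibble(
    dplyr::bind_cols(tibble::tibble(id = fp$ids), tibble::as_tibble(coords)),
    class = "odor_embedding"
  )
  attr(out, "umap_params") <- list(dims = dims, seed = seed,
                                   n_neighbors = n_neighbors,
                                   min_dist = min_dist, metric = metric)
  out
}

embedding_coords <- function(emb) {
  cols <- setdiff(names(emb), "id")
  m <- as.matrix(emb[cols])
  rownames(m) <- emb$id
  m
}

#' @export
print.odor_embedding <- function(x, ...) {
  p <- attr(x, "umap_params")
  cat("<odor_embedding> ", nrow(x), " molecules in ", p$dims,
      "D (metric ", p$metric, ", n_neighbors ", p$n_neighbors,
      ", min_dist ", p$min_dist, ", seed ", p$seed, ")\n", sep = "")
  NextMethod()
}
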