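# Clustering of the embedded chemical space: k-means, self-organizing
# maps, and cluster-number selection (elbow + Kelley penalty).

new_cluster_assignment <- function(ids, labels, method, level, grid = NULL,
                                   extra = list()) {
  out <- tibble::new_tibble(
    tibble::tibble(id = ids, cluster = as.integer(labels)),
    class = "cluster_assignment"
  )
  attr(out, "method") <- method
  attr(out, "level") <- as.integer(level)
  attr(out, "grid") <- grid
  attr(out, "effective_clusters") <- length(unique(labels))
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  g <- attr(x, "grid")
  cat("<cluster_assignment> ", attr(x, "method"),
      if (!is.null(g)) paste0(" ", g[1], "x", g[2]) else "",
      ", level ", attr(x, "level"), ", ",
      attr(x, "effective_clusters"), " effective cluster(s), ",
      nrow(x), " molecules\n", sep = "")
  NextMethod()
}

#' k-means clustering of an embedding
#'
#' Best-of-restarts Lloyd k-means on the embedded coordinates: every
#' observation joins the cluster with the nearest mean, and the restart
#' with the smallest within-cluster sum of squares wins. Deterministic
#' for a fixed seed; every cluster is non-empty. Cluster indices are
#' 1-based.
#'
#' @param emb An `odor_embedding`.
#' @param k Number of clusters (1 <= k <= n).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 20).
#' @return A `cluster_assignment` with attributes `wss` (total
#'   within-cluster sum of squares) and `centers`.
#' @export
cluster_kmeans <- function(emb, k, seed = 42L, n_restarts = 20L) {
  coords <- embedding_coords(emb)
  if (k < 1) abort("k must be >= 1.", class = "odorspace_parameter_error")
  if (k > nrow(coords)) {
    abort("k cannot exceed the number of molecules.",
          class = "odorspace_parameter_error")
  }
  if (k == nrow(coords)) {  # singleton clusters: exact, WSS = 0
    return(new_cluster_assignment(emb$id, seq_len(k), "kmeans", level = k,
                                  extra = list(wss = 0, centers = coords)))
  }
  set.seed(seed)
  fit <- suppressWarnings(
    stats::kmeans(coords, centers = k, nstart = n_restarts, iter.max = 100L)
  )
  new_cluster_assignment(emb$id, fit$cluster, "kmeans", level = k,
                         extra = list(wss = fit$tot.withinss,
                                      centers = fit$centers))
}

#' Self-organizing map clustering of an embedding
#'
#' Online Kohonen training on a rectangular grid of units with a
#' Gaussian neighbourhood: the learning rate decays linearly from
#' `alpha[1]` to `alpha[2]` and the neighbourhood radius from half the
#' larger grid dimension to 0.5 over the presentation schedule. Each
#' molecule is assigned to its best-matching unit; units that attract no
#' molecules are legitimate, so the number of effective clusters can be
#' smaller than the grid. Unit indices are 1-based, row-major.
#'
#' @param emb An `odor_embedding`.
#' @param grid_rows,grid_cols Grid dimensions (grid size >= 2 units).
#' @param epochs Training epochs (full passes over the data; default
#'   500).
#' @param seed Integer seed (controls prototype initialisation and the
#'   presentation order).
#' @param alpha Length-2 learning-rate schedule (start, end).
#' @return A `cluster_assignment` with attributes `prototypes`,
#'   `qe` (per-epoch mean quantization error) and `grid`.
#' @export
cluster_som <- function(emb, grid_rows = 4L, grid_cols = 4L, epochs = 500L,
                        seed = 42L, alpha = c(0.5, 0.01)) {
  coords <- embedding_coords(emb)
  n <- nrow(coords)
  m <- grid_rows * grid_cols
  if (m < 2) {
    abort("The SOM grid needs at least 2 units.",
          class = "odorspace_parameter_error")
  }
  if (epochs < 1) {
    abort("epochs must be >= 1.", class = "odorspace_parameter_error")
  }
  set.seed(seed)
  init_idx <- sample(n, m, replace = n < m)
  proto <- coords[init_idx, , drop = FALSE]
  order <- matrix(0L, nrow = epochs, ncol = n)
  for (e in seq_len(epochs)) order[e, ] <- sample(n) - 1L
  grid_pos <- as.matrix(expand.grid(col = seq_len(grid_cols),
                                    row = seq_len(grid_rows))[, c("row", "col")])
  radius0 <- max(grid_rows, grid_cols) / 2
  fit <- som_train_cpp(coords, proto, order, grid_pos,
                       alpha[1], alpha[2], radius0, 0.5)
  new_cluster_assignment(emb$id, fit$labels, "som", level = m,
                         grid = c(grid_rows, grid_cols),
                         extra = list(prototypes = fit$prototypes,
                                      qe = fit$qe,
                                      bmu_dist = fit$bmu_dist))
}

#' Cluster-number selection by elbow curve and Kelley penalty
#'
#' For every candidate k, partitions the embedding (k-means,
#' best-of-restarts) and computes the within-cluster sum of squares
#' (elbow curve) and the Kelley penalty: the partition spread is the
#' mean over clusters of size >= 2 of the cluster's mean pairwise member
#' distance; spreads are min-max normalised over the evaluated range to
#' `[1, length(k_range) - 1]` and the penalty adds k. The optimum is the
#' penalty argmin, ties resolved toward the smallest k.
#'
#' @param emb An `odor_embedding`.
#' @param k_range Candidate cluster counts (each >= 2).
#' @param seed Integer seed.
#' @param n_restarts k-means restarts per k.
#' @return A `cluster_selection` tibble with columns `k`, `wss`,
#'   `spread`, `norm_spread`, `penalty` and the attribute `k_optimal`.
#' @export
select_cluster_count <- function(emb, k_range = 2:10, seed = 42L,
                                 n_restarts = 20L) {
  if (length(k_range) == 0 || any(k_range < 2)) {
    abort("k_range must be non-empty with every k >= 2.",
          class = "odorspace_parameter_error")
  }
  k_range <- sort(unique(as.integer(k_range)))
  coords <- embedding_coords(emb)
  dmat <- as.matrix(stats::dist(coords))

  rows <- purrr::map(k_range, function(k) {
    asg <- cluster_kmeans(emb, k, seed = derive_seed(seed, paste0("k", k)),
                          n_restarts = n_restarts)
    spreads <- purrr::map_dbl(split(seq_len(nrow(coords)), asg$cluster),
                              function(ix) {
                                if (length(ix) < 2) return(NA_real_)
                                mean(dmat[ix, ix][upper.tri(diag(length(ix)))])
                              })
    spreads <- spreads[!is.na(spreads)]
    tibble::tibble(k = k, wss = attr(asg, "wss"),
                   spread = if (length(spreads) > 0) mean(spreads) else NA_real_)
  })
  report <- dplyr::bind_rows(rows)
  undefined <- is.na(report$spread)
  if (any(undefined)) {
    warn(paste0("Spread undefined (all clusters singletons) at k = ",
                paste(report$k[undefined], collapse = ", "),
                "; excluded from the penalty."))
  }
  s <- report$spread
  rng <- range(s, na.rm = TRUE)
  K <- length(k_range)
  norm <- if (diff(rng) == 0) rep(1, length(s)) else {
    1 + (s - rng[1]) / diff(rng) * (K - 2)
  }
  report$norm_spread <- norm
  report$penalty <- report$norm_spread + report$k
  ok <- which(!is.na(report$penalty))
  k_opt <- report$k[ok[which.min(report$penalty[ok])]]
  out <- tibble::new_tibble(report, class = "cluster_selection")
  attr(out, "k_optimal") <- k_opt
  attr(out, "k_range") <- k_range
  out
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("<cluster_selection> optimal k = ", attr(x, "k_optimal"), "\n", sep = "")
  NextMethod()
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), about 0 for unrelated
#' ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return A number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Permutation-stable cluster labels
#'
#' Relabels clusters in order of first appearance, for comparing
#' assignments that differ only by label permutation.
#'
#' @param labels Integer label vector.
#' @return Integer vector with labels 1..k in first-appearance order.
#' @export
canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}
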