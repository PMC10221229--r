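two_blobs <- function(n_per = 5, sep = 20, seed = 9) {
  set.seed(seed)
  coords <- rbind(
    matrix(stats::rnorm(n_per * 3), ncol = 3),
    matrix(stats::rnorm(n_per * 3), ncol = 3) + sep)
  embedding_from_coords(coords)
}

# k-means -------------------------------------------------------------

test_that("k-means hits the exhaustive optimum on small instances", {
  set.seed(31)
  emb <- embedding_from_coords(matrix(stats::rnorm(30), ncol = 3))
  coords <- as.matrix(emb[c("x", "y", "z")])
  for (k in 2:3) {
    asg <- cluster_kmeans(emb, k, seed = 1, n_restarts = 50)
    expect_equal(attr(asg, "wss"), exhaustive_min_wss(coords, k),
                 tolerance = 1e-8)
  }
})

test_that("k-means honours the degenerate ends of k", {
  emb <- two_blobs()
  coords <- as.matrix(emb[c("x", "y", "z")])
  one <- cluster_kmeans(emb, 1, seed = 1)
  expect_equal(length(unique(one$cluster)), 1L)
  expect_equal(attr(one, "wss"), sum(scale(coords, scale = FALSE)^2))
  all_k <- cluster_kmeans(emb, nrow(emb), seed = 1)
  expect_equal(attr(all_k, "wss"), 0)
  expect_equal(attr(all_k, "effective_clusters"), nrow(emb))
  expect_error(cluster_kmeans(emb, 0), class = "odorspace_parameter_error")
  expect_error(cluster_kmeans(emb, nrow(emb) + 1),
               class = "odorspace_parameter_error")
})

test_that("two well-separated blobs are recovered exactly", {
  emb <- two_blobs()
  asg <- cluster_kmeans(emb, 2, seed = 4)
  expect_equal(adjusted_rand_index(asg$cluster, rep(1:2, each = 5)), 1)
})

# self-organizing map -------------------------------------------------

test_that("the SOM respects its grid and improves quantization error", {
  emb <- synthetic_bundle()$embedding
  som <- cluster_som(emb, 4, 4, epochs = 100, seed = 2)
  expect_lte(attr(som, "effective_clusters"), 16L)
  expect_true(all(som$cluster >= 1 & som$cluster <= 16))
  qe <- attr(som, "qe")
  expect_lt(qe[length(qe)], qe[1])
  again <- cluster_som(emb, 4, 4, epochs = 100, seed = 2)
  expect_identical(som$cluster, again$cluster)
})

test_that("SOM and k-means agree on trivially separable data", {
  emb <- two_blobs()
  som <- cluster_som(emb, 2, 1, epochs = 50, seed = 7)
  km <- cluster_kmeans(emb, 2, seed = 7)
  expect_equal(adjusted_rand_index(som$cluster, km$cluster), 1)
  expect_equal(attr(som, "effective_clusters"), 2L)
})

test_that("degenerate SOM inputs behave", {
  emb <- embedding_from_coords(matrix(c(1, 2, 3), ncol = 3))
  som <- cluster_som(emb, 1, 2, epochs = 5, seed = 1)
  expect_equal(length(unique(som$cluster)), 1L)
  expect_error(cluster_som(two_blobs(), 1, 1),
               class = "odorspace_parameter_error")
  expect_error(cluster_som(two_blobs(), 2, 2, epochs = 0),
               class = "odorspace_parameter_error")
})

# cluster-number selection --------------------------------------------

test_that("the Kelley penalty recovers the four planted families", {
  b <- synthetic_bundle()
  sel <- select_cluster_count(b$embedding, 2:10, seed = 13)
  expect_equal(attr(sel, "k_optimal"), 4L)
  expect_true(all(diff(sel$wss) <= 1e-6))  # elbow curve non-increasing
  expect_true(all(sel$norm_spread >= 1 - 1e-9 &
                    sel$norm_spread <= length(2:10) - 1 + 1e-9))
})

test_that("a structureless blob gives a penalty rising beyond its minimum", {
  set.seed(17)
  emb <- embedding_from_coords(matrix(stats::rnorm(300, sd = 1), ncol = 3))
  sel <- select_cluster_count(emb, 2:8, seed = 3)
  i_opt <- match(attr(sel, "k_optimal"), sel$k)
  expect_true(all(diff(sel$penalty[i_opt:nrow(sel)]) > 0))
  expect_lt(attr(sel, "k_optimal"), max(sel$k))
  expect_true(all(diff(sel$wss) <= 0))
})

test_that("duplicating every point leaves the optimum unchanged", {
  b <- synthetic_bundle()
  emb <- b$embedding
  dup <- embedding_from_coords(
    rbind(as.matrix(emb[c("x", "y", "z")]),
          as.matrix(emb[c("x", "y", "z")])),
    ids = c(emb$id, paste0(emb$id, "_dup")))
  sel <- select_cluster_count(emb, 2:8, seed = 19)
  sel_dup <- select_cluster_count(dup, 2:8, seed = 19)
  expect_equal(attr(sel_dup, "k_optimal"), attr(sel, "k_optimal"))
})

test_that("SOM clustering at the selected optimum recovers the families", {
  b <- synthetic_bundle()
  sel <- select_cluster_count(b$embedding, 2:10, seed = 13)
  g <- ceiling(sqrt(attr(sel, "k_optimal")))
  som <- cluster_som(b$embedding, g, attr(sel, "k_optimal") / g, seed = 23)
  expect_gte(adjusted_rand_index(som$cluster, b$dataset$family), 0.6)
})

test_that("our adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:5, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2) * 10L), 0)
  expect_equal(adjusted_rand_index(rep(1:2, 5), rep(2:1, 5)), 1)
})

test_that("downstream labels are permutation-invariant", {
  labels <- c(3L, 3L, 1L, 2L, 1L)
  perm <- c(2L, 2L, 3L, 1L, 3L)
  expect_equal(canonicalize_labels(labels), canonicalize_labels(perm))
})
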