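triangle <- rbind(c(0, 0, 0), c(2.2, 0, 0), c(1.1, 3.1, 0))

test_that("a planted acceptor-acceptor-hydrophobe triangle is recovered", {
  rot <- rotation_matrix(c(1, 2, 0.5), 1.1)
  jitter <- rbind(c(0.1, -0.1, 0.05), c(-0.08, 0.12, 0), c(0, 0.05, -0.1))
  u1 <- make_unit("m1", c("A", "A", "H"), list(triangle))
  u2 <- make_unit("m2", c("A", "A", "H"),
                  list(sweep((triangle + jitter) %*% rot, 2, c(5, -3, 2), "+")))
  hs <- search_common_hypotheses(list(u1, u2), match_fraction = 1)
  expect_gt(length(hs), 0L)
  top <- hs[[1]]
  expect_equal(top$signature, "AAH")
  expect_equal(nrow(top$matched), 2L)
  expect_equal(top$distance_matrix["A1", "A2"], 2.2, tolerance = 1e-6)
  expect_true(all(top$matched$rmsd <= 2))
  # exhaustive oracle agrees that both molecules realise the triangle
  expect_true(all(oracle_matches(list(u1, u2), top$features$kind,
                                 as.matrix(top$features[, c("x", "y", "z")]),
                                 2)))
})

test_that("molecules with disjoint feature kinds share no hypothesis", {
  u1 <- make_unit("m1", c("A", "A", "A"), list(triangle))
  u2 <- make_unit("m2", c("H", "H", "H"), list(triangle + 10))
  expect_message(hs <- search_common_hypotheses(list(u1, u2),
                                                match_fraction = 1),
                 "No common-feature hypothesis")
  expect_length(hs, 0L)
})

test_that("the search matches exhaustive enumeration on small instances", {
  # three molecules, two conformers each, planted AAH core + one decoy
  # feature per molecule placed far away so it cannot join any match
  rot2 <- rotation_matrix(c(0, 1, 1), 0.7)
  rot3 <- rotation_matrix(c(1, 0, 0), 2.0)
  jit <- function(seed) {
    set.seed(seed)
    matrix(stats::runif(9, -0.15, 0.15), 3, 3)
  }
  mk <- function(id, rot, shift, decoy_kind, seed) {
    core1 <- (triangle + jit(seed)) %*% rot
    core2 <- (triangle + jit(seed + 50)) %*% rot
    decoy <- matrix(c(30, 30, 30), 1, 3) + seed
    make_unit(id, c("A", "A", "H", decoy_kind),
              list(sweep(rbind(core1, decoy), 2, shift, "+"),
                   sweep(rbind(core2, decoy), 2, shift, "+")))
  }
  units <- list(mk("m1", diag(3), c(0, 0, 0), "H", 1),
                mk("m2", rot2, c(4, 1, -2), "A", 2),
                mk("m3", rot3, c(-3, 2, 5), "H", 3))
  hs <- search_common_hypotheses(units, match_fraction = 1,
                                 max_hypotheses = 100L)
  got <- unique(vapply(hs, `[[`, character(1), "signature"))
  oracle <- oracle_survivors(units, min_features = 3L, tolerance = 2,
                             match_fraction = 1)
  expect_setequal(got, names(oracle))
  for (h in hs) {
    expect_equal(nrow(h$matched), oracle[[h$signature]])
    # re-verify every reported match exactly
    expect_true(all(oracle_matches(
      units[match(h$matched$id, vapply(units, `[[`, character(1), "id"))],
      h$features$kind, as.matrix(h$features[, c("x", "y", "z")]),
      h$tolerance)))
  }
})

test_that("scores are bounded and coverage never dips below the floor", {
  ens <- component_ensembles(c("IA", "WL"))
  for (hs in list(find_common_pharmacophores(ens$IA),
                  find_common_pharmacophores(ens, match_fraction = 0.5))) {
    for (h in hs) {
      expect_gt(h$score, 0)
      expect_lte(h$score, 1)
      expect_gte(nrow(h$matched) / h$n_units, 0.5)
      expect_gte(nrow(h$features), 3L)
      expect_lte(nrow(h$features), 6L)
    }
  }
})

test_that("the conformer-space pharmacophore of isoamyl acetate shows the ester acceptor pair", {
  ens <- component_ensembles(c("IA", "WL"))
  hs <- find_common_pharmacophores(ens$IA)
  expect_gt(length(hs), 0L)
  d <- acceptor_pair_distance(hs)
  expect_true(abs(d - 2.303) <= 0.15)
})

test_that("signatures, distances and scores are rigid-motion invariant", {
  ens <- component_ensembles(c("IA", "WL"))
  rot <- rotation_matrix(c(0.3, 1, -0.2), 0.9)
  shift <- c(12, -7, 3)
  moved <- ens$IA
  moved$coords <- lapply(moved$coords, function(cc)
    sweep(cc %*% rot, 2, shift, "+"))
  a <- find_common_pharmacophores(ens$IA)
  b <- find_common_pharmacophores(moved)
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_equal(a[[i]]$signature, b[[i]]$signature)
    expect_equal(a[[i]]$score, b[[i]]$score, tolerance = 1e-6)
    expect_equal(a[[i]]$distance_matrix, b[[i]]$distance_matrix,
                 tolerance = 1e-6)
    expect_equal(a[[i]]$matched$rmsd, b[[i]]$matched$rmsd, tolerance = 1e-6)
  }
})

test_that("interfeature distances obey plane geometry", {
  u1 <- make_unit("m1", c("A", "H", "R"),
                  list(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))))
  hs <- search_common_hypotheses(list(u1, u1), match_fraction = 1)
  top <- hs[[1]]
  d <- interfeature_distances(top)
  expect_setequal(round(d$distance, 6), c(3, 4, 5))
  expect_equal(nrow(d), 3L)
  expect_true(all(c("A1", "H2", "R3") %in% c(d$from, d$to)))
})

test_that("degenerate inputs are rejected", {
  expect_error(find_common_pharmacophores(list()),
               class = "odorspace_parameter_error")
  ens <- component_ensembles(c("IA", "WL"))
  expect_error(find_common_pharmacophores(ens$IA, min_features = 2L))
})
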