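# Shared fixtures, built once per test run and memoised.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- build()
  fixture_cache[[key]]
}

table1 <- function() memo("table1", odor_table1)

# Small four-family synthetic dataset with its fingerprints and 3D
# embedding, shared by the clustering and statistics tests.
synthetic_bundle <- function() {
  memo("synthetic", function() {
    ds <- generate_odorants(generator_config(seed = 101L))
    fp <- compute_fingerprints(ds)
    emb <- embed_umap(fp, seed = 101L)
    list(dataset = ds, fp = fp, embedding = emb)
  })
}

# Conformer ensembles of the mixture components used repeatedly.
component_ensembles <- function(ids = c("IA", "WL")) {
  key <- paste0("ens_", paste(sort(ids), collapse = "_"))
  memo(key, function() {
    t1 <- table1()
    generate_conformers(t1[match(ids, t1$id), c("id", "smiles")],
                        target_count = 50L, seed = 42L)
  })
}

# A hand-made toy dataset: five molecules in two clusters with simple
# note sets, used for the profile and co-occurrence arithmetic.
toy_dataset <- function() {
  memo("toy", function() {
    odor_dataset(tibble::tibble(
      id = paste0("m", 1:5),
      name = paste0("m", 1:5),
      smiles = c("CCO", "CCC", "CCN", "CCCl", "CCCC"),
      notes = list(c("fruity", "sweet"), c("fruity", "green"),
                   c("fruity"), c("fruity", "sweet"), c("woody"))
    ), min_note_occurrence = 1L)
  })
}

toy_assignment <- function() {
  ds <- toy_dataset()
  structure(
    tibble::new_tibble(
      tibble::tibble(id = ds$id, cluster = c(1L, 1L, 1L, 2L, 2L)),
      class = "cluster_assignment"),
    method = "kmeans", level = 2L, effective_clusters = 2L)
}

# Build a synthetic search unit for the common-pharmacophore engine
# from bare feature kinds and coordinates.
make_unit <- function(id, kinds, positions, conformer = NA_integer_) {
  template <- tibble::tibble(
    label = paste0(kinds, seq_along(kinds)), kind = kinds,
    x = positions[[1]][, 1], y = positions[[1]][, 2],
    z = positions[[1]][, 3],
    source_atoms = as.list(seq_along(kinds)),
    normal = vector("list", length(kinds)))
  list(id = id, conformer = conformer, kinds = kinds,
       positions = positions, template = template,
       n_conformers = length(positions))
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
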