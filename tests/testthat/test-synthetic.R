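test_that("generation is deterministic for a fixed seed", {
  a <- generate_odorants(generator_config(seed = 5L))
  b <- generate_odorants(generator_config(seed = 5L))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- generate_odorants(generator_config(seed = 6L))
  expect_false(identical(a$smiles, c$smiles))
})

test_that("a degenerate one-note family emits only that note", {
  fam <- family_spec("only", scaffolds = "{1}C(=O)O{2}",
                     substituents = c("C", "CC", "CCC", "CCCC"),
                     note_distribution = c(fruity = 1), size = 10)
  cfg <- generator_config(families = list(only = fam), noise_rate = 0,
                          notes_per_molecule = c(1L, 3L), seed = 3L)
  ds <- generate_odorants(cfg, min_note_occurrence = 1L)
  expect_true(all(vapply(ds$notes, identical, logical(1), "fruity")))
})

test_that("family and family-typical notes are strongly associated", {
  ds <- synthetic_bundle()$dataset
  sig <- c(esters = "fruity", vanilloids = "vanilla",
           lactones = "coconut", ionones = "woody")
  for (fam in names(sig)) {
    carries <- vapply(ds$notes, function(n) sig[[fam]] %in% n, logical(1))
    tab <- table(ds$family == fam, carries)
    expect_lt(suppressWarnings(stats::chisq.test(tab))$p.value, 0.01)
    # enrichment: the signature note is more frequent inside the family
    expect_gt(mean(carries[ds$family == fam]),
              mean(carries[ds$family != fam]))
  }
})

test_that("the default configuration retains at least 90% of note types", {
  ds <- synthetic_bundle()$dataset
  emitted <- unique(unlist(ds$notes))
  retained <- intersect(emitted, dataset_vocabulary(ds))
  expect_gte(length(retained) / length(emitted), 0.9)
  # every retained note really occurs at least five times
  counts <- note_occurrences(ds)
  expect_true(all(counts$n[counts$note %in% retained] >= 5L))
})

test_that("note counts respect the configured range before pruning", {
  ds <- synthetic_bundle()$dataset
  expect_true(all(lengths(ds$notes) >= 1L & lengths(ds$notes) <= 5L))
  expect_true(mean(lengths(ds$notes) >= 2L) > 0.95)  # dedup may shrink rarely
})

test_that("impossible chemistry or oversized families fail loudly", {
  bad <- family_spec("broken", scaffolds = "{1}Q(=O)O{2}",
                     substituents = c("C", "CC"),
                     note_distribution = c(x = 1), size = 2)
  expect_error(
    generate_odorants(generator_config(families = list(broken = bad)),
                      min_note_occurrence = 1L),
    class = "odorspace_generation_error")
  too_big <- family_spec("big", scaffolds = "{1}C(=O)O{2}",
                         substituents = c("C", "CC"),
                         note_distribution = c(x = 1), size = 50)
  expect_error(
    generate_odorants(generator_config(families = list(big = too_big)),
                      min_note_occurrence = 1L),
    class = "odorspace_generation_error")
})

test_that("planting the components injects them once, idempotently", {
  ds <- synthetic_bundle()$dataset
  planted <- plant_mixture_components(ds)
  expect_equal(nrow(planted), nrow(ds) + 7L)
  v_notes <- planted$notes[[match("V", planted$id)]]
  expect_setequal(v_notes, c("sweet", "vanilla", "creamy", "chocolate"))
  again <- plant_mixture_components(planted)
  expect_equal(nrow(again), nrow(planted))
  expect_false(anyDuplicated(again$id) > 0)
})

test_that("an id collision is renamed, not overwritten", {
  ds <- synthetic_bundle()$dataset
  clash <- tibble::as_tibble(ds)[1, ]
  clash$id <- "V"  # same id as vanillin, different structure
  ds2 <- odor_dataset(clash, min_note_occurrence = 1L, canonicalise = FALSE)
  expect_message(planted <- plant_mixture_components(ds2), "collision")
  expect_true("V_planted" %in% planted$id)
  expect_equal(nrow(planted), 8L)
})
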