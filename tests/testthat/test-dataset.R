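test_that("the bundled component table loads with its published notes", {
  t1 <- table1()
  expect_s3_class(t1, "odor_dataset")
  expect_equal(nrow(t1), 7L)
  wl <- t1$notes[[match("WL", t1$id)]]
  expect_length(wl, 11L)  # raw notes incl. the two sub-threshold ones
  expect_true(all(c("maple", "lovage") %in% wl))
  # the composite descriptor splits into two notes
  bi <- t1$notes[[match("bI", t1$id)]]
  expect_true(all(c("powdery", "orris") %in% bi))
  expect_length(bi, 11L)
})

test_that("reading a CSV normalises, deduplicates and canonicalises", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,name,smiles,notes",
    "a,ethanol,OCC,Sweet; sweet;  Fresh",
    "b,broken,notasmiles,Green",
    "c,ethanol2,C(C)O,Fresh; green"
  ), path)
  expect_warning(ds <- read_odorant_table(path, min_note_occurrence = 1L),
                 "unparsable SMILES")
  expect_equal(nrow(ds), 2L)
  expect_equal(attr(ds, "skipped")$id, "b")
  expect_equal(ds$notes[[1]], c("sweet", "fresh"))
  # two spellings of ethanol agree after canonicalisation
  expect_equal(ds$smiles[1], ds$smiles[2])
})

test_that("missing columns and empty tables are configuration errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,notes", "a,x,Sweet"), path)
  expect_error(read_odorant_table(path), class = "odorspace_config_error")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,name,smiles,notes", path2)
  expect_error(read_odorant_table(path2), class = "odorspace_empty_dataset")
})

test_that("write then read round-trips records exactly", {
  t1 <- table1()
  path <- withr::local_tempfile(fileext = ".csv")
  write_odorant_table(t1, path)
  back <- read_odorant_table(path, min_note_occurrence = 1L)
  expect_equal(back$id, t1$id)
  expect_equal(back$smiles, t1$smiles)
  expect_equal(back$notes, t1$notes)
})

test_that("vocabulary keeps exactly the notes at or above the threshold", {
  recs <- tibble::tibble(
    id = paste0("m", 1:6), name = paste0("m", 1:6),
    smiles = rep("CCO", 6),
    notes = c(rep(list(c("common", "shared")), 4),
              list(c("common", "rare")), list("common")))
  # threshold 1: everything
  expect_setequal(build_vocabulary(recs, 1L), c("common", "shared", "rare"))
  # rare occurs 1 < 5, shared occurs 4 < 5
  expect_equal(build_vocabulary(recs, 5L), "common")
  expect_setequal(build_vocabulary(recs, 4L), c("common", "shared"))
  expect_error(build_vocabulary(recs, 0L))
})

test_that("external counts override observed occurrences", {
  t1 <- table1()
  vocab <- dataset_vocabulary(t1)
  expect_false(any(c("maple", "lovage") %in% vocab))
  expect_true("tonka" %in% vocab)
  # rebuilt on the pruned dataset the vocabulary is a fixed point
  pruned <- prune_notes(t1)
  expect_setequal(build_vocabulary(pruned, 1L), vocab)
})

test_that("the mixture note union reproduces the published counts", {
  t1 <- table1()
  u <- mixture_note_union(c("V", "IA", "F", "EA", "bD", "bI", "WL"), t1)
  expect_length(u, 39L)
  expect_length(mixture_note_union(c("bD", "bI"), t1), 18L)
  # single-component union is that component's pruned notes
  expect_equal(mixture_note_union("V", t1),
               sort(record_notes <- t1$notes[[match("V", t1$id)]]))
  expect_error(mixture_note_union("nope", t1),
               class = "odorspace_lookup_error")
})

test_that("common notes are symmetric, bounded and match the text", {
  t1 <- table1()
  expect_equal(common_notes(t1, "bD", "bI"),
               sort(c("fruity", "sweet", "floral", "raspberry")))
  expect_equal(common_notes(t1, "IA", "EA"), c("fruity", "sweet"))
  for (a in t1$id) {
    expect_equal(common_notes(t1, a, a),
                 sort(intersect(t1$notes[[match(a, t1$id)]],
                                dataset_vocabulary(t1))))
    for (b in t1$id) {
      ab <- common_notes(t1, a, b)
      expect_equal(ab, common_notes(t1, b, a))
      expect_lte(length(ab), min(lengths(t1$notes[match(c(a, b), t1$id)])))
    }
  }
})

test_that("mixture fixtures validate their proportions", {
  m <- odor_mixtures()
  expect_equal(sum(m$RC$proportions), 100)
  expect_length(m$"WL/IA"$components, 2L)
  expect_error(mixture_fixture("bad", c("a", "b"), c(60, 30)),
               class = "odorspace_config_error")
  expect_silent(mixture_fixture("ok", c("a", "b"), c(60.2, 39.9)))
})

test_that("the note panel surfaces the stated counts", {
  pool <- note_pool()
  expect_length(pool, 55L)
  expect_equal(attr(pool, "stated_frequent"), 25L)
  expect_equal(attr(pool, "stated_mixture"), 39L)
  expect_equal(attr(pool, "stated_shared"), 10L)
})

test_that("the subset membership fixture is complete", {
  t3 <- odor_table3()
  expect_setequal(unique(t3$reference_id),
                  c("V", "WL", "F", "bI", "bD", "IA", "EA"))
  with_smiles <- t3$smiles[!is.na(t3$smiles)]
  expect_false(anyNA(canonical_smiles(with_smiles)))
})
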