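# A small world of candidates around a reference with the isoamyl
# acetate note profile.
subset_world <- function(candidates) {
  recs <- tibble::tibble(
    id = c("ref", names(candidates)),
    name = c("ref", names(candidates)),
    smiles = rep("CCO", length(candidates) + 1L),
    notes = c(list(c("sweet", "fruity", "banana", "solvent", "pear")),
              unname(candidates)))
  odor_dataset(recs, min_note_occurrence = 1L)
}

test_that("similarity descriptors match the hand count", {
  ds <- subset_world(list(cand = c("sweet", "fruity", "banana", "apple")))
  s <- profile_similarity(ds, "ref", "cand")
  expect_equal(s$n_common, 3L)
  expect_equal(s$n_noncommon, 1L)
  expect_equal(s$pct_common, 60)
  expect_equal(s$pct_noncommon, 25)
})

test_that("identical and disjoint note sets sit at the extremes", {
  ds <- subset_world(list(
    twin = c("sweet", "fruity", "banana", "solvent", "pear"),
    alien = c("woody", "smoky")))
  twin <- profile_similarity(ds, "ref", "twin")
  expect_equal(twin$n_noncommon, 0L)
  expect_equal(twin$pct_common, 100)
  alien <- profile_similarity(ds, "ref", "alien")
  expect_equal(alien$n_common, 0L)
})

test_that("the union convention changes only the denominators", {
  ds <- subset_world(list(cand = c("sweet", "fruity", "banana", "apple")))
  s <- profile_similarity(ds, "ref", "cand", convention = "union")
  expect_equal(s$n_common, 3L)
  expect_equal(s$pct_common, 100 * 3 / 6)
  expect_equal(s$pct_noncommon, 100 * 1 / 6)
})

test_that("the hard rule keeps the boundary and rejects below it", {
  ds <- subset_world(list(
    boundary = c("sweet", "fruity", "banana", "woody", "smoky"),  # 3 / 2
    short = c("sweet", "fruity"),                                 # 2 common
    noisy = c("sweet", "fruity", "banana", "a", "b", "c")))       # 3 noncommon
  res <- select_subset(ds, "ref", members = c("boundary", "short", "noisy"))
  expect_equal(res$selected_ids, c("ref", "boundary"))
  audit <- res$audit
  expect_true(audit$pass_hard_rule[audit$candidate_id == "boundary"])
  expect_match(audit$reason[audit$candidate_id == "short"], "common notes")
  expect_match(audit$reason[audit$candidate_id == "noisy"], "noncommon")
})

test_that("over-full selections keep the smallest pct_noncommon", {
  # 14 hard-rule survivors with pairwise distinct pct_noncommon, built
  # from (n_common, n_noncommon) pairs against a 10-note reference
  ref_notes <- paste0("r", 1:10)
  pairs <- list(c(5, 0), c(10, 1), c(9, 1), c(8, 1), c(7, 1), c(6, 1),
                c(5, 1), c(9, 2), c(4, 1), c(7, 2), c(3, 1), c(5, 2),
                c(4, 2), c(3, 2))
  cands <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    c(ref_notes[seq_len(p[1])],
      if (p[2] > 0) paste0("x", i, "_", seq_len(p[2])))
  })
  names(cands) <- sprintf("c%02d", seq_along(pairs))  # ascending pct_noncommon
  recs <- tibble::tibble(
    id = c("ref", names(cands)), name = c("ref", names(cands)),
    smiles = rep("CCO", length(cands) + 1L),
    notes = c(list(ref_notes), unname(cands)))
  ds <- odor_dataset(recs, min_note_occurrence = 1L)
  pct <- vapply(names(cands), function(cc)
    profile_similarity(ds, "ref", cc)$pct_noncommon, numeric(1))
  expect_equal(anyDuplicated(pct), 0L)
  res <- select_subset(ds, "ref", members = names(cands))
  expect_equal(sum(res$audit$pass_hard_rule), 14L)
  expect_length(res$selected_ids, 11L)  # reference + cap
  expect_setequal(setdiff(res$selected_ids, "ref"),
                  names(sort(pct))[1:10])
})

test_that("selection is deterministic and audits every candidate", {
  b <- synthetic_bundle()
  ds <- b$dataset
  members <- ds$id[ds$family == "esters"][1:40]
  ref <- members[1]
  r1 <- select_subset(ds, ref, members = members[-1])
  r2 <- select_subset(ds, ref, members = members[-1])
  expect_identical(r1$selected_ids, r2$selected_ids)
  expect_identical(r1$audit, r2$audit)
  expect_setequal(r1$audit$candidate_id, members[-1])
  expect_equal(anyDuplicated(r1$audit$candidate_id), 0L)
  expect_lte(length(r1$selected_ids), 11L)
})

test_that("gaining a shared note never worsens the outcome", {
  base_notes <- c("sweet", "fruity", "woody")
  improved <- c(base_notes, "banana")
  ds <- subset_world(list(base = base_notes, better = improved))
  s_base <- profile_similarity(ds, "ref", "base")
  s_imp <- profile_similarity(ds, "ref", "better")
  expect_gte(s_imp$n_common, s_base$n_common)
  expect_equal(s_imp$n_noncommon, s_base$n_noncommon)
  expect_gte(s_imp$pct_common, s_base$pct_common)
  expect_lte(s_imp$pct_noncommon, s_base$pct_noncommon)
  res <- select_subset(ds, "ref", members = c("base", "better"))
  if ("base" %in% res$selected_ids) {
    expect_true("better" %in% res$selected_ids)
  }
})

test_that("an empty selection explains each failure", {
  ds <- subset_world(list(a = c("woody"), b = c("smoky", "tar")))
  res <- select_subset(ds, "ref", members = c("a", "b"))
  expect_equal(res$selected_ids, "ref")
  expect_equal(nrow(res$audit), 2L)
  expect_true(all(!res$audit$pass_hard_rule))
  expect_true(all(grepl("common", res$audit$reason)))
})
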