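test_that("profile arithmetic matches direct counting on the toy set", {
  stats <- note_profiles(toy_dataset(), toy_assignment())
  # fruity occurs on 4 molecules, 3 of them in cluster 1 (of size 3)
  fr1 <- stats[stats$note == "fruity" & stats$cluster == 1L, ]
  expect_equal(fr1$n_in_cluster, 3L)
  expect_equal(fr1$n_total, 4L)
  expect_equal(fr1$cluster_size, 3L)
  expect_equal(fr1$pct_ON, 75)
  expect_equal(fr1$pct_OM, 100)
  # woody is carried only by a cluster-2 molecule
  expect_equal(stats$pct_ON[stats$note == "woody" & stats$cluster == 2L], 100)
  # zero counts are present as explicit rows
  expect_equal(stats$n_in_cluster[stats$note == "woody" & stats$cluster == 1L],
               0L)
  expect_equal(nrow(stats),
               length(dataset_vocabulary(toy_dataset())) * 2L)
})

test_that("pct_ON partitions to 100 over clusters for every note", {
  b <- synthetic_bundle()
  asg <- cluster_som(b$embedding, 4, 4, epochs = 100, seed = 3)
  stats <- note_profiles(b$dataset, asg)
  sums <- dplyr::summarise(dplyr::group_by(stats, .data$note),
                           s = sum(.data$pct_ON), .groups = "drop")
  expect_true(all(abs(sums$s - 100) <= 0.1))
  expect_true(all(stats$pct_OM >= 0 & stats$pct_OM <= 100))
  # pct_OM = 100 iff every molecule of the cluster carries the note
  full <- stats[stats$pct_OM == 100, ]
  expect_true(all(full$n_in_cluster == full$cluster_size))
})

test_that("profiles are invariant under cluster relabeling", {
  ds <- toy_dataset()
  asg <- toy_assignment()
  perm <- asg
  perm$cluster <- c(2L, 2L, 2L, 1L, 1L)[match(asg$id, perm$id)]
  a <- note_profiles(ds, asg)
  b <- note_profiles(ds, perm)
  b$cluster <- c(2L, 1L)[b$cluster]  # undo the relabeling
  b <- dplyr::arrange(b, .data$note, .data$cluster)
  expect_equal(as.data.frame(dplyr::arrange(a, .data$note, .data$cluster)),
               as.data.frame(b))
})

test_that("a note absent from the dataset is flagged, not NaN", {
  w <- capture_warnings(
    stats <- note_profiles(toy_dataset(), toy_assignment(),
                           notes = c("fruity", "phantom")))
  expect_true(any(grepl("phantom", w)))
  expect_true(all(is.na(stats$pct_ON[stats$note == "phantom"])))
  expect_false(any(is.nan(stats$pct_ON)))
})

test_that("co-occurrence counts match their definition on toys", {
  ds <- odor_dataset(tibble::tibble(
    id = c("x", "y", "z"), name = c("x", "y", "z"),
    smiles = c("CCO", "CCC", "CCCC"),
    notes = list(c("a", "b"), c("a", "b"), c("c"))
  ), min_note_occurrence = 1L)
  cc <- cooccurrence(ds)
  expect_equal(cc$counts["a", "b"], 2)
  expect_equal(cc$counts["a", "a"], 2)
  expect_equal(cc$relative["a", "b"], 100)
  expect_equal(cc$counts["a", "c"], 0)  # disjoint notes never co-occur
  expect_equal(cc$relative["c", "a"], 0)
  expect_true(isSymmetric(cc$counts))
  expect_equal(diag(cc$relative), c(a = 100, b = 100, c = 100))
})

test_that("the component table yields the hand-counted fruity/sweet pair", {
  cc <- cooccurrence(table1())
  # IA, F, EA, bD, bI carry both fruity and sweet
  expect_equal(cc$counts["fruity", "sweet"], 5)
})

test_that("co-occurrence equals a brute-force double loop", {
  b <- synthetic_bundle()
  ds <- b$dataset[1:50, ]
  notes <- sort(unique(unlist(ds$notes)))
  cc <- cooccurrence(ds, notes = notes)
  brute <- matrix(0L, length(notes), length(notes),
                  dimnames = list(notes, notes))
  for (m in seq_len(nrow(ds))) {
    nn <- ds$notes[[m]]
    for (i in nn) for (j in nn) brute[i, j] <- brute[i, j] + 1L
  }
  expect_equal(unname(cc$counts), unname(brute))
  # weighting identity: relative[i,j] * counts[i,i] == relative[j,i] * counts[j,j]
  lhs <- cc$relative * diag(cc$counts)
  expect_equal(lhs, t(lhs))
})

test_that("per-cluster count matrices sum to the whole-dataset matrix", {
  b <- synthetic_bundle()
  asg <- cluster_kmeans(b$embedding, 4, seed = 3)
  notes <- dataset_vocabulary(b$dataset)
  total <- cooccurrence(b$dataset, notes = notes)$counts
  parts <- lapply(sort(unique(asg$cluster)), function(cl) {
    suppressWarnings(
      cooccurrence(b$dataset, notes = notes, restrict_to = cl,
                   assignment = asg)$counts)
  })
  expect_equal(Reduce(`+`, parts), total)
})

test_that("restriction flags notes missing from the cluster", {
  ds <- toy_dataset()
  asg <- toy_assignment()
  expect_warning(
    cc <- cooccurrence(ds, restrict_to = 2L, assignment = asg),
    "zero occurrences")
  expect_true(all(is.na(cc$relative["green", ])))
  expect_equal(cc$counts["woody", "woody"], 1)
})

test_that("top notes are ordered by count with alphabetical ties", {
  ds <- toy_dataset()
  expect_equal(top_frequent_notes(ds, 1L), "fruity")
  expect_equal(top_frequent_notes(ds, 4L),
               c("fruity", "sweet", "green", "woody"))
  expect_error(top_frequent_notes(ds, 99L),
               class = "odorspace_parameter_error")
  ties <- odor_dataset(tibble::tibble(
    id = c("u", "v"), name = c("u", "v"), smiles = c("CCO", "CCC"),
    notes = list(c("zesty", "airy"), c("zesty", "airy"))
  ), min_note_occurrence = 1L)
  expect_equal(top_frequent_notes(ties, 2L), c("airy", "zesty"))
})

test_that("exports are one-decimal, radar/heatmap-shaped tables", {
  stats <- note_profiles(toy_dataset(), toy_assignment())
  path <- withr::local_tempfile(fileext = ".csv")
  export_profile_tables(stats, path)
  wide <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(wide, c("note", "cluster_1", "cluster_2"))
  expect_equal(wide$cluster_1[wide$note == "fruity"], 75)
  cc <- cooccurrence(toy_dataset())
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_heatmap_tables(cc, path2)
  hm <- readr::read_csv(path2, show_col_types = FALSE)
  expect_equal(nrow(hm), length(cc$notes))
  expect_equal(hm$fruity[hm$note == "sweet"], 100)
})
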