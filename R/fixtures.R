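# Bundled reference fixtures: the seven aroma-mixture components with
# their published odor notes, the odor-profile subset membership lists,
# and the curated note panels used by the synthetic generator.

# Notes known from the source database to occur fewer than five times
# (flagged in the component table's footnote); they are excluded from the
# vocabulary even though this excerpt cannot count them itself.
TABLE1_LOW_OCCURRENCE_NOTES <- c("maple", "lovage")

#' The seven mixture-component odorants
#'
#' The components of the two studied aroma mixtures as a ready-made
#' dataset: the six "red cordial" (RC) blending-mixture molecules
#' (vanillin, isoamyl acetate, frambinone, ethyl acetate,
#' beta-damascenone, beta-ionone) and whiskey lactone, which together
#' with isoamyl acetate forms the woody masking mixture (WL/IA). SMILES
#' are curated from the CAS numbers. The composite descriptor
#' "powdery orris" is split into the two notes "powdery" and "orris".
#'
#' The vocabulary excludes "maple" and "lovage" (whiskey-lactone notes
#' known to occur fewer than five times in the parent database), so the
#' pruned note union over all seven components has 39 notes.
#'
#' @return An `odor_dataset` of 7 records.
#' @export
odor_table1 <- function() {
  path <- pkg_file("extdata", "table1.csv")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df$notes <- lapply(df$notes, parse_notes)
  all_notes <- unique(unlist(df$notes))
  ext <- stats::setNames(rep(5L, length(all_notes)), all_notes)
  ext[TABLE1_LOW_OCCURRENCE_NOTES] <- 1L
  odor_dataset(df, min_note_occurrence = 5L, external_counts = ext)
}

#' The two studied aroma mixtures
#'
#' `RC` is the six-component blending mixture perceived as a grenadine
#' syrup odor, with the published component percentages; `WL/IA` is the
#' binary masking mixture in which the woody note of whiskey lactone
#' dominates isoamyl acetate.
#'
#' @return Named list of two [mixture_fixture()] objects, `RC` and
#'   `WL/IA`.
#' @export
odor_mixtures <- function() {
  list(
    "RC" = mixture_fixture(
      "RC",
      components = c("V", "F", "IA", "bI", "EA", "bD"),
      proportions = c(41.8, 41.8, 5.0, 4.3, 4.3, 2.8)
    ),
    "WL/IA" = mixture_fixture("WL/IA", components = c("WL", "IA"))
  )
}

#' Odor-profile subset membership lists
#'
#' For each cluster containing a mixture component, the published list of
#' molecules whose odor profile resembles that component (the "-s"
#' subsets used for common-feature pharmacophore generation). SMILES are
#' curated from the molecule names; entries whose trade names do not
#' identify a unique structure carry `NA`.
#'
#' @return Tibble with columns `cluster`, `reference_id`, `subset`,
#'   `member`, `smiles`.
#' @export
odor_table3 <- function() {
  path <- pkg_file("extdata", "table3.csv")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  na = "NA")
}

#' Curated odor-note panel
#'
#' The 55-note panel combining the most frequent notes of a large odorant
#' database with the notes of the two mixtures. The source text states 55
#' notes made of 25 frequent plus 39 mixture notes with 10 shared — which
#' arithmetically gives 54; both counts are kept as stated and the
#' discrepancy is surfaced in the returned attributes rather than
#' resolved. The panel is also the default global note pool of the
#' synthetic generator.
#'
#' @return Character vector of 55 notes with attributes
#'   `stated_frequent` (25), `stated_mixture` (39), `stated_shared` (10).
#' @export
note_pool <- function() {
  mixture_notes <- sort(unique(unlist(odor_table1()$notes)))
  mixture_notes <- setdiff(mixture_notes, TABLE1_LOW_OCCURRENCE_NOTES)
  extra_frequent <- c(
    "spicy", "balsamic", "caramellic", "herbal", "minty", "fatty",
    "waxy", "oily", "pineapple", "sulfurous", "citrus", "fresh",
    "earthy", "honey", "jammy", "tallow"
  )
  pool <- sort(unique(c(mixture_notes, extra_frequent)))
  structure(pool,
            stated_frequent = 25L, stated_mixture = 39L, stated_shared = 10L)
}
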