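# Synthetic odorant-database generator.
#
# Molecules are built by template substitution: each structural family
# owns a set of scaffold SMILES templates with numbered attachment slots
# ("{1}", "{2}") and a substituent fragment pool; every scaffold x
# substituent combination is enumerated, canonicalised and deduplicated,
# and the family's members are sampled from that combinatorial space.
# This guarantees valid, family-coherent chemistry (no random molecular
# graphs). Odor notes are drawn from family-conditional distributions
# with an optional popularity-weighted noise admixture from the global
# pool, so families carry recognisable note signatures on top of a
# realistic shared background.

#' Define a structural family for the generator
#'
#' @param name Family name (used as ground-truth label and id prefix).
#' @param scaffolds Character vector of SMILES templates containing
#'   `{1}` (and optionally `{2}`) attachment slots.
#' @param substituents Character vector of SMILES fragments substituted
#'   into the slots.
#' @param note_distribution Named numeric vector: note -> emission
#'   weight in `[0, 1]`, used as sampling weights for the family's notes.
#' @param size Number of molecules to draw from the family (>= 1).
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, scaffolds, substituents, note_distribution, size) {
  stopifnot(is_string(name), is.character(scaffolds), is.character(substituents),
            is.numeric(note_distribution), !is.null(names(note_distribution)),
            size >= 1)
  if (any(note_distribution < 0 | note_distribution > 1)) {
    abort("Note emission weights must lie in [0, 1].",
          class = "odorspace_config_error")
  }
  structure(list(name = name, scaffolds = scaffolds,
                 substituents = substituents,
                 note_distribution = note_distribution,
                 size = as.integer(size)),
            class = "family_spec")
}

alkyl_pool <- function() {
  c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC",
    "CC(C)C", "CCC(C)C", "CC(C)CC", "C/C=C/C", "CCCCCC(C)C")
}

#' Default structural families
#'
#' Four families emulating well-populated regions of odorant chemical
#' space: aliphatic esters (fruity), vanilloid phenolics (vanilla),
#' aliphatic lactones (coconut) and ionone-like terpenoids
#' (woody/violet). Their note distributions concentrate each family's
#' signature notes while sharing broad descriptors such as sweet and
#' fruity.
#'
#' @return Named list of [family_spec()] objects.
#' @export
default_families <- function() {
  list(
    esters = family_spec(
      "esters",
      scaffolds = c("{1}C(=O)O{2}", "{1}C(=O)OC(C){2}"),
      substituents = alkyl_pool(),
      note_distribution = c(
        fruity = 0.95, sweet = 0.6, banana = 0.4, pear = 0.4, apple = 0.4,
        green = 0.3, ethereal = 0.25, pineapple = 0.25, tropical = 0.25,
        winey = 0.2, brandy = 0.2, solvent = 0.2, sharp = 0.15
      ),
      size = 150
    ),
    vanilloids = family_spec(
      "vanilloids",
      scaffolds = c("COc1cc({1})ccc1O", "CCOc1cc({1})ccc1O",
                    "COc1cc({1})ccc1OC", "Oc1ccc({1})cc1",
                    "COc1ccc({1})cc1", "COc1cc({1})ccc1OC(C)=O"),
      substituents = c("C=O", "C(C)=O", "CC=O", "CC(C)=O", "CCC(C)=O",
                       "/C=C/C(C)=O", "/C=C/C=O", "CO", "CCO",
                       "COC(C)=O", "CC(O)C", "C", "CC", "CCC", "COC=O"),
      note_distribution = c(
        vanilla = 0.9, sweet = 0.8, creamy = 0.5, balsamic = 0.35,
        spicy = 0.3, chocolate = 0.25, powdery = 0.25, caramellic = 0.2,
        honey = 0.15, woody = 0.15
      ),
      size = 80
    ),
    lactones = family_spec(
      "lactones",
      scaffolds = c("{1}C1CCC(=O)O1", "{1}C1CCCC(=O)O1", "{1}C1OC(=O)CC1C",
                    "{1}C1COC(=O)C1", "{1}C1OC(=O)C(C)C1", "{1}C1CCC(=O)OC1"),
      substituents = alkyl_pool(),
      note_distribution = c(
        coconut = 0.8, lactonic = 0.7, sweet = 0.45, creamy = 0.4,
        coumarinic = 0.3, tonka = 0.25, fruity = 0.25, celery = 0.15,
        toasted = 0.15, nutty = 0.15, caramellic = 0.15, oily = 0.12,
        waxy = 0.12, burnt = 0.12
      ),
      size = 75
    ),
    ionones = family_spec(
      "ionones",
      scaffolds = c("{1}/C=C/C1=C(C)CCCC1(C)C", "{1}/C=C/C1C(C)=CCCC1(C)C",
                    "{1}/C=C/C1=C(C)CC(C)CC1(C)C", "{1}/C=C/C1C(C)=CC(C)CC1(C)C",
                    "{1}C(=O)C1=C(C)CCCC1(C)C", "{1}C(=O)C1C(C)=CCCC1(C)C"),
      substituents = c("CC(=O)", "CCC(=O)", "CC(O)", "CCC(O)",
                       "CC(OC(C)=O)", "COC(=O)", "C", "CC"),
      note_distribution = c(
        woody = 0.8, floral = 0.7, violet = 0.45, sweet = 0.35,
        fruity = 0.35, raspberry = 0.3, orris = 0.25, berry = 0.25,
        dry = 0.25, powdery = 0.22, tobacco = 0.22, rose = 0.2,
        tea = 0.2, plum = 0.2
      ),
      size = 44
    )
  )
}

#' Background family of mixed functionality
#'
#' Assorted alcohols, aldehydes, ketones, ethers, alkylbenzenes and
#' sulfur compounds with a broad, unfocused note distribution; used to
#' pad datasets with molecules that belong to no signature family.
#'
#' @param size Number of background molecules.
#' @return A [family_spec()].
#' @export
background_family <- function(size = 60) {
  family_spec(
    "background",
    scaffolds = c("{1}CO", "{1}C=O", "{1}C(C)=O", "c1ccccc1{1}",
                  "{1}C1CCCCC1", "{1}c1ccncc1", "{1}CS"),
    substituents = alkyl_pool(),
    note_distribution = c(
      green = 0.4, fresh = 0.35, herbal = 0.35, citrus = 0.3, sweet = 0.3,
      fruity = 0.3, earthy = 0.25, nutty = 0.2, fatty = 0.2, waxy = 0.2,
      oily = 0.2, sulfurous = 0.15, minty = 0.15, ripe = 0.1
    ),
    size = size
  )
}

#' Generator configuration
#'
#' @param families List of [family_spec()] objects (default: the four
#'   signature families of [default_families()]).
#' @param background_size Number of background molecules appended (0
#'   disables the background family; the default, so the stock
#'   configuration is a pure four-family benchmark).
#' @param notes_per_molecule Integer range (length 2) of notes drawn per
#'   molecule before pruning.
#' @param noise_rate Probability that a drawn note comes from the
#'   popularity-weighted global pool instead of the family distribution.
#' @param seed Integer seed; one sub-stream is derived per family so the
#'   draw for one family does not depend on the others.
#' @return A `generator_config` list.
#' @export
generator_config <- function(families = default_families(),
                             background_size = 0,
                             notes_per_molecule = c(2L, 5L),
                             noise_rate = 0.05,
                             seed = 1L) {
  stopifnot(length(notes_per_molecule) == 2,
            notes_per_molecule[1] >= 1,
            notes_per_molecule[1] <= notes_per_molecule[2],
            noise_rate >= 0, noise_rate <= 1)
  if (background_size > 0) {
    families <- c(families, list(background = background_family(background_size)))
  }
  structure(list(families = families,
                 notes_per_molecule = as.integer(notes_per_molecule),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "generator_config")
}

# Enumerate the combinatorial space of one family: every scaffold x
# substituent tuple, canonicalised and deduplicated.
enumerate_family <- function(fam) {
  combos <- list()
  for (sc in fam$scaffolds) {
    two_slots <- grepl("{2}", sc, fixed = TRUE)
    if (two_slots) {
      grid <- expand.grid(a = fam$substituents, b = fam$substituents,
                          stringsAsFactors = FALSE)
      smi <- vapply(seq_len(nrow(grid)), function(i) {
        gsub("{2}", grid$b[i], gsub("{1}", grid$a[i], sc, fixed = TRUE),
             fixed = TRUE)
      }, character(1))
    } else {
      smi <- vapply(fam$substituents, function(a) {
        gsub("{1}", a, sc, fixed = TRUE)
      }, character(1), USE.NAMES = FALSE)
    }
    can <- canonical_smiles(smi)
    if (anyNA(can)) {
      abort(paste0("Family '", fam$name, "': template '", sc,
                   "' produced invalid chemistry for substituent(s): ",
                   paste(smi[is.na(can)], collapse = ", ")),
            class = "odorspace_generation_error")
    }
    combos[[sc]] <- can
  }
  unique(unlist(combos, use.names = FALSE))
}

draw_notes <- function(fam_dist, pool_weights, n_range, noise_rate) {
  n <- sample(seq(n_range[1], n_range[2]), 1L)
  n_fam <- min(n, length(fam_dist))
  k_noise <- stats::rbinom(1L, n_fam, noise_rate)
  k_fam <- n_fam - k_noise
  drawn <- character()
  if (k_fam > 0) {
    drawn <- sample(names(fam_dist), k_fam, prob = fam_dist)
  }
  if (k_noise > 0) {
    avail <- setdiff(names(pool_weights), drawn)
    w <- pool_weights[avail]
    if (length(avail) > 0 && sum(w) > 0) {
      drawn <- c(drawn, sample(avail, min(k_noise, length(avail)), prob = w))
    }
  }
  unique(drawn)
}

#' Generate a synthetic odorant dataset
#'
#' Deterministic for a fixed seed: each family draws its structures and
#' notes from its own derived sub-stream. Every molecule records its
#' generating family as ground truth for clustering-recovery tests.
#'
#' @param config A [generator_config()].
#' @param min_note_occurrence Vocabulary pruning threshold applied to the
#'   generated dataset.
#' @return An `odor_dataset` with a `family` column.
#' @export
generate_odorants <- function(config = generator_config(),
                              min_note_occurrence = 5L) {
  stopifnot(inherits(config, "generator_config"))
  # popularity-weighted global pool: pooled family emission mass, so the
  # noise admixture reproduces the heavy-tailed marginals of real
  # databases instead of flattening them
  pool_weights <- numeric()
  for (fam in config$families) {
    w <- fam$note_distribution * fam$size
    for (nm in names(w)) {
      prev <- if (nm %in% names(pool_weights)) pool_weights[[nm]] else 0
      pool_weights[nm] <- prev + w[[nm]]
    }
  }

  seen <- character()
  out <- list()
  for (fam in config$families) {
    set.seed(derive_seed(config$seed, paste0("structures_", fam$name)))
    space <- enumerate_family(fam)
    space <- setdiff(space, seen)
    if (length(space) < fam$size) {
      abort(paste0("Family '", fam$name, "' can only produce ",
                   length(space), " distinct molecules but size = ",
                   fam$size, "."),
            class = "odorspace_generation_error")
    }
    smiles <- sample(space, fam$size)
    seen <- c(seen, smiles)

    set.seed(derive_seed(config$seed, paste0("notes_", fam$name)))
    notes <- replicate(fam$size,
                       draw_notes(fam$note_distribution, pool_weights,
                                  config$notes_per_molecule, config$noise_rate),
                       simplify = FALSE)
    ids <- sprintf("%s_%03d", fam$name, seq_len(fam$size))
    out[[fam$name]] <- tibble::tibble(
      id = ids, name = ids, cas = NA_character_, smiles = smiles,
      notes = notes, family = fam$name
    )
  }
  records <- dplyr::bind_rows(out)
  odor_dataset(records, min_note_occurrence = min_note_occurrence,
               canonicalise = FALSE)
}

#' Inject the mixture-component odorants into a dataset
#'
#' Adds the bundled mixture components (or any `odor_dataset` of real
#' molecules) to a synthetic dataset so downstream stages can locate
#' them. Id collisions are resolved by suffixing the incoming id (and
#' reported); re-injecting an identical record is a no-op, so the
#' operation is idempotent.
#'
#' @param dataset Target `odor_dataset`.
#' @param components Records to inject (default [odor_table1()]).
#' @return The augmented `odor_dataset` (vocabulary rebuilt).
#' @export
plant_mixture_components <- function(dataset, components = odor_table1()) {
  recs <- tibble::as_tibble(dataset)
  inc <- tibble::as_tibble(components)
  if (!"family" %in% names(inc)) inc$family <- "planted"
  if (!"family" %in% names(recs)) recs$family <- NA_character_
  keep <- rep(TRUE, nrow(inc))
  for (i in seq_len(nrow(inc))) {
    j <- match(inc$id[i], recs$id)
    if (!is.na(j)) {
      if (identical(recs$smiles[j], inc$smiles[i])) {
        keep[i] <- FALSE  # already planted
      } else {
        new_id <- paste0(inc$id[i], "_planted")
        inform(paste0("Id collision on '", inc$id[i], "': renamed to '",
                      new_id, "'."))
        inc$id[i] <- new_id
      }
    }
  }
  merged <- dplyr::bind_rows(recs, inc[keep, , drop = FALSE])
  odor_dataset(merged,
               min_note_occurrence = attr(dataset, "min_note_occurrence") %||% 5L,
               canonicalise = FALSE)
}
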