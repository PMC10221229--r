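# End-to-end orchestration: dataset -> fingerprints -> embedding ->
# clustering -> odor statistics -> subset selection -> pharmacophores,
# from a single configuration with one global seed expanded
# deterministically per stage, and a manifest recording parameters and
# output checksums.

#' Default pipeline configuration
#'
#' A compact end-to-end demonstration: simulate the four-family
#' synthetic database, plant the seven real mixture components, embed
#' and cluster, profile the vocabulary over the SOM clusters, select
#' odor-profile subsets around planted references, and build
#' single-molecule pharmacophores plus their pairwise alignments.
#'
#' @param output_dir Where stage outputs are written.
#' @param seed Global seed.
#' @return A configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(output_dir = tempfile("odorspace_run_"),
                                    seed = 1L) {
  list(
    seed = seed,
    output_dir = output_dir,
    dataset = list(simulate = TRUE, background_size = 0,
                   plant_components = TRUE, min_note_occurrence = 5),
    embedding = list(n_neighbors = 15, min_dist = 0.1, metric = "jaccard"),
    cluster = list(methods = c("kmeans", "som"), levels = c(4, 9, 16),
                   k_range = c(2, 10)),
    profiles = list(method = "som", level = 16, top_notes = 25),
    selection = list(references = c("V", "IA", "WL"), cap = 10),
    pharmacophore = list(single_molecule = c("WL", "IA"),
                         common = list(c("WL", "IA")),
                         target_conformers = 25, energy_window_kj = 21)
  )
}

known_config_keys <- c("seed", "output_dir", "dataset", "embedding",
                       "cluster", "profiles", "selection", "pharmacophore")

validate_config <- function(config) {
  unknown <- setdiff(names(config), known_config_keys)
  missing <- setdiff(c("seed", "output_dir", "dataset"), names(config))
  problems <- c(
    if (length(unknown) > 0)
      paste0("unknown section(s): ", paste(unknown, collapse = ", ")),
    if (length(missing) > 0)
      paste0("missing required section(s): ", paste(missing, collapse = ", "))
  )
  if (length(problems) > 0) {
    abort(paste0("Invalid pipeline configuration: ",
                 paste(problems, collapse = "; ")),
          class = "odorspace_config_error")
  }
  config
}

som_grid_for_level <- function(level) {
  r <- floor(sqrt(level))
  while (level %% r != 0) r <- r - 1
  c(r, level / r)
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage in order, writing one or more plain
#' files per stage under `output_dir`; a failure aborts with the stage
#' named. Returns (and writes) a manifest of the configuration, derived
#' per-stage seeds, and the path + MD5 checksum of every output, so a
#' rerun can be verified to reproduce identical files.
#'
#' @param config Configuration list (see [default_pipeline_config()])
#'   or the path of a YAML file holding one.
#' @return A `run_manifest` list, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is_string(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  st <- new.env(parent = emptyenv())
  st$outputs <- list()
  st$seeds <- list()
  st$assignments <- list()
  st$subsets <- list()
  st$hypotheses <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(config$output_dir, name)
    writer(path)
    st$outputs[[length(st$outputs) + 1L]] <- tibble::tibble(
      stage = stage, path = path,
      md5 = unname(tools::md5sum(path)))
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "odorspace_pipeline_error")
    })
  }

  # dataset ---------------------------------------------------------------
  ds_cfg <- config$dataset
  dataset <- stage("dataset", {
    if (isTRUE(ds_cfg$simulate)) {
      st$seeds$dataset <- derive_seed(seed, "dataset")
      cfg <- generator_config(background_size = ds_cfg$background_size %||% 0,
                              seed = st$seeds$dataset)
      d <- generate_odorants(cfg,
                             min_note_occurrence = ds_cfg$min_note_occurrence %||% 5)
    } else {
      d <- read_odorant_table(ds_cfg$csv,
                              min_note_occurrence = ds_cfg$min_note_occurrence %||% 5)
    }
    if (isTRUE(ds_cfg$plant_components)) d <- plant_mixture_components(d)
    d
  })
  emit("dataset", "dataset.csv", function(p) write_odorant_table(dataset, p))

  # fingerprints / embedding ----------------------------------------------
  emb_cfg <- config$embedding %||% list()
  st$seeds$embedding <- derive_seed(seed, "embedding")
  embedding <- stage("embedding", {
    fp <- compute_fingerprints(dataset)
    embed_umap(fp, seed = st$seeds$embedding,
               n_neighbors = emb_cfg$n_neighbors %||% 15,
               min_dist = emb_cfg$min_dist %||% 0.1,
               metric = emb_cfg$metric %||% "jaccard")
  })
  emit("embedding", "embedding.csv",
       function(p) readr::write_csv(tibble::as_tibble(embedding), p,
                                    progress = FALSE))

  # clustering ------------------------------------------------------------
  cl_cfg <- config$cluster %||% list()
  stage("cluster", {
    kr <- cl_cfg$k_range %||% c(2, 10)
    st$seeds$cluster <- derive_seed(seed, "cluster")
    selection <- select_cluster_count(embedding, seq(kr[1], kr[2]),
                                      seed = st$seeds$cluster)
    emit("cluster", "cluster_selection.csv",
         function(p) readr::write_csv(tibble::as_tibble(selection), p,
                                      progress = FALSE))
    for (method in cl_cfg$methods %||% c("kmeans", "som")) {
      for (level in cl_cfg$levels %||% c(4, 9, 16)) {
        nm <- paste0(method, level)
        asg <- if (method == "kmeans") {
          cluster_kmeans(embedding, level,
                         seed = derive_seed(seed, paste0("kmeans", level)))
        } else {
          g <- som_grid_for_level(level)
          cluster_som(embedding, g[1], g[2],
                      seed = derive_seed(seed, paste0("som", level)))
        }
        st$assignments[[nm]] <- asg
        emit("cluster", paste0("assignment_", nm, ".csv"), function(p) {
          df <- tibble::as_tibble(asg)
          df$method <- method
          df$level <- level
          readr::write_csv(df, p, progress = FALSE)
        })
      }
    }
  })

  # odor-note statistics ---------------------------------------------------
  pr_cfg <- config$profiles %||% list()
  profile_assignment <- st$assignments[[paste0(pr_cfg$method %||% "som",
                                            pr_cfg$level %||% 16)]]
  if (!is.null(profile_assignment)) {
    stage("profiles", {
      stats <- note_profiles(dataset, profile_assignment)
      emit("profiles", "note_profiles.csv",
           function(p) readr::write_csv(tibble::as_tibble(stats), p,
                                        progress = FALSE))
      emit("profiles", "profiles_pctON.csv",
           function(p) export_profile_tables(stats, p, "pct_ON"))
      top <- top_frequent_notes(dataset,
                                min(pr_cfg$top_notes %||% 25,
                                    length(dataset_vocabulary(dataset))))
      cooc <- cooccurrence(dataset, notes = top)
      emit("profiles", "cooccurrence_relative.csv",
           function(p) export_heatmap_tables(cooc, p))
    })
  }

  # subset selection -------------------------------------------------------
  sel_cfg <- config$selection %||% list()
  if (length(sel_cfg$references %||% character()) > 0 &&
      !is.null(profile_assignment)) {
    stage("selection", {
      for (ref in sel_cfg$references) {
        if (!ref %in% dataset$id) next
        cl <- profile_assignment$cluster[match(ref, profile_assignment$id)]
        res <- select_subset(dataset, ref, assignment = profile_assignment,
                             cluster = cl, cap = sel_cfg$cap %||% 10)
        st$subsets[[ref]] <- res
        emit("selection", paste0("subset_", ref, ".csv"),
             function(p) readr::write_csv(res$audit, p, progress = FALSE))
      }
    })
  }

  # pharmacophores ---------------------------------------------------------
  ph_cfg <- config$pharmacophore %||% list()
  if (length(ph_cfg$single_molecule %||% character()) > 0 ||
      length(ph_cfg$common %||% list()) > 0) {
    stage("pharmacophore", {
      st$seeds$pharmacophore <- derive_seed(seed, "pharmacophore")
      wanted <- unique(c(ph_cfg$single_molecule %||% character(),
                         unlist(ph_cfg$common %||% list())))
      wanted <- wanted[wanted %in% dataset$id]
      if (length(wanted) > 0) {
        ens <- generate_conformers(
          dataset[match(wanted, dataset$id), c("id", "smiles")],
          target_count = ph_cfg$target_conformers %||% 50,
          energy_window_kj = ph_cfg$energy_window_kj %||% 21,
          seed = st$seeds$pharmacophore)
        for (id in intersect(ph_cfg$single_molecule %||% character(), wanted)) {
          hs <- find_common_pharmacophores(ens[[id]])
          st$hypotheses[[paste0(id, "-c")]] <- hs
          emit("pharmacophore", paste0("hypotheses_", id, "-c.json"),
               function(p) write_hypotheses(hs, p))
        }
        for (pair in ph_cfg$common %||% list()) {
          if (!all(pair %in% wanted)) next
          nm <- paste(pair, collapse = "-")
          hs <- find_common_pharmacophores(ens[pair], match_fraction = 1)
          st$hypotheses[[nm]] <- hs
          emit("pharmacophore", paste0("hypotheses_", nm, ".json"),
               function(p) write_hypotheses(hs, p))
        }
        singles <- intersect(ph_cfg$single_molecule %||% character(), wanted)
        if (length(singles) >= 2) {
          rows <- list()
          for (i in seq_len(length(singles) - 1)) {
            for (j in seq(i + 1, length(singles))) {
              hi <- st$hypotheses[[paste0(singles[i], "-c")]]
              hj <- st$hypotheses[[paste0(singles[j], "-c")]]
              if (length(hi) == 0 || length(hj) == 0) next
              al <- align_hypotheses(hi[[1]], hj[[1]])
              rows[[length(rows) + 1L]] <- tibble::tibble(
                reference = singles[i], other = singles[j],
                success = al$success, rmsd = al$rmsd)
            }
          }
          if (length(rows) > 0) {
            emit("pharmacophore", "hypothesis_alignments.csv",
                 function(p) readr::write_csv(dplyr::bind_rows(rows), p,
                                              progress = FALSE))
          }
        }
      }
    })
  }

  manifest <- structure(
    list(config = config, seeds = st$seeds,
         outputs = dplyr::bind_rows(st$outputs)),
    class = "run_manifest")
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(
    list(config = config, seeds = st$seeds,
         outputs = dplyr::bind_rows(st$outputs)),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inform(paste0("Pipeline complete: ", nrow(manifest$outputs),
                " output file(s) in ", config$output_dir))
  invisible(manifest)
}

#' Serialise a hypothesis set to JSON
#'
#' @param hypotheses A `hypothesis_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_hypotheses <- function(hypotheses, path) {
  payload <- purrr::map(unclass(hypotheses), function(h) {
    list(id = h$id, signature = h$signature, score = h$score,
         tolerance = h$tolerance, n_units = h$n_units,
         features = h$features[c("label", "kind", "x", "y", "z")],
         matched = h$matched,
         distances = interfeature_distances(h))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
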