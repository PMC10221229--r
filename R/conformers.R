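# Conformer-ensemble generation.
#
# Ensembles are produced by a distance-geometry embedding (ETKDG) with
# force-field minimisation (MMFF94, UFF fallback), an energy window
# relative to the ensemble minimum, and heavy-atom RMSD deduplication.
# The geometry engine runs in a Python/RDKit subprocess shipped with
# the package; the R side owns the job description, determinism
# contract and all downstream use of the coordinates.

python_path <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    abort("python was not found on the PATH.", class = "odorspace_missing_tool")
  }
  p
}

#' Generate force-field conformer ensembles
#'
#' For every molecule: embed up to `2 * target_count` trial geometries
#' under a fixed seed, minimise each with MMFF94 (UFF when MMFF
#' parameters are missing), keep conformers within `energy_window_kj`
#' of the ensemble minimum, deduplicate at heavy-atom RMSD
#' `rms_dedup`, and retain at most `target_count` conformers in
#' ascending energy order. Deterministic for a fixed seed.
#'
#' @param molecules A data frame with `id` and `smiles` columns, an
#'   `odor_dataset`, a named character vector of SMILES, or a single
#'   SMILES string.
#' @param target_count Target ensemble size (default 50).
#' @param energy_window_kj Energy window above the minimum, kJ/mol
#'   (default 21).
#' @param seed Integer seed for the embedding.
#' @param rms_dedup Heavy-atom RMSD below which two conformers count as
#'   duplicates, in Angstrom (default 0.5).
#' @return A `conformer_set`: named list of `conformer_ensemble`
#'   objects (fields `molecule_id`, `atoms`, `bonds`, `coords` — one
#'   atoms x 3 matrix per conformer — `rel_energy_kj`, `forcefield`).
#' @export
generate_conformers <- function(molecules, target_count = 50L,
                                energy_window_kj = 21, seed = 42L,
                                rms_dedup = 0.5) {
  mols <- normalize_molecule_input(molecules)
  stopifnot(target_count >= 1, energy_window_kj > 0)

  job <- tempfile(fileext = ".json")
  sdf <- tempfile(fileext = ".sdf")
  meta_file <- tempfile(fileext = ".json")
  on.exit(unlink(c(job, sdf, meta_file)), add = TRUE)

  jsonlite::write_json(
    list(seed = seed, target_count = target_count,
         energy_window_kj = energy_window_kj, rms_dedup = rms_dedup,
         molecules = purrr::map2(mols$id, mols$smiles,
                                 ~ list(id = .x, smiles = .y))),
    job, auto_unbox = TRUE, digits = NA
  )
  status <- system2(python_path(),
                    c(pkg_file("python", "conformers.py"), job, sdf, meta_file),
                    stdout = FALSE, stderr = "")
  if (status != 0) {
    abort("The conformer backend exited with an error.",
          class = "odorspace_conformer_error")
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  failed <- meta$id[meta$status != "ok"]
  if (length(failed) > 0) {
    abort(paste0("Conformer embedding failed for molecule(s): ",
                 paste(failed, collapse = ", ")),
          class = "odorspace_conformer_error")
  }
  parse_conformer_sdf(sdf, mols)
}

normalize_molecule_input <- function(molecules) {
  if (is.character(molecules)) {
    ids <- names(molecules) %||% paste0("mol", seq_along(molecules))
    ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
    mols <- tibble::tibble(id = ids, smiles = unname(molecules))
  } else {
    stopifnot(all(c("id", "smiles") %in% names(molecules)))
    mols <- tibble::tibble(id = as.character(molecules$id),
                           smiles = molecules$smiles)
  }
  if (anyDuplicated(mols$id)) {
    abort("Duplicate molecule ids.", class = "odorspace_parameter_error")
  }
  mols
}

parse_conformer_sdf <- function(sdf, mols) {
  set <- ChemmineR::read.SDFset(sdf)
  blocks <- ChemmineR::datablock(set)
  out <- list()
  for (i in seq_along(set)) {
    db <- blocks[[i]]
    names(db) <- sub("\\s.*$", "", names(db))  # drop SD-tag index annotations
    mol_id <- db[["MOL_ID"]]
    ab <- ChemmineR::atomblock(set[[i]])
    bb <- ChemmineR::bondblock(set[[i]])
    coords <- unname(ab[, 1:3, drop = FALSE])
    element <- gsub("_.*$", "", rownames(ab))
    if (is.null(out[[mol_id]])) {
      out[[mol_id]] <- list(
        molecule_id = mol_id,
        smiles = mols$smiles[match(mol_id, mols$id)],
        atoms = tibble::tibble(idx = seq_along(element), element = element),
        bonds = tibble::tibble(a1 = as.integer(bb[, 1]),
                               a2 = as.integer(bb[, 2]),
                               order = as.integer(bb[, 3])),
        coords = list(), rel_energy_kj = numeric(),
        forcefield = db[["FORCEFIELD"]]
      )
    }
    k <- length(out[[mol_id]]$coords) + 1L
    out[[mol_id]]$coords[[k]] <- coords
    out[[mol_id]]$rel_energy_kj[k] <- as.numeric(db[["REL_ENERGY_KJ"]])
  }
  out <- purrr::map(out, function(e) structure(e, class = "conformer_ensemble"))
  structure(out[order(match(names(out), mols$id))], class = "conformer_set")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", x$molecule_id, ": ", length(x$coords),
      " conformer(s), ", nrow(x$atoms), " atoms, ", x$forcefield,
      ", energy span ", round(max(x$rel_energy_kj), 2), " kJ/mol\n", sep = "")
  invisible(x)
}

#' @export
print.conformer_set <- function(x, ...) {
  cat("<conformer_set> ", length(x), " molecule(s)\n", sep = "")
  for (e in x) print(e)
  invisible(x)
}

#' Extract one conformer as a 3D molecule
#'
#' @param ensemble A `conformer_ensemble`.
#' @param conformer Conformer index (default 1, the lowest-energy one).
#' @return A `molecule_3d` list: `atoms`, `bonds`, `coords`.
#' @export
molecule_3d <- function(ensemble, conformer = 1L) {
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            conformer >= 1, conformer <= length(ensemble$coords))
  structure(list(molecule_id = ensemble$molecule_id,
                 atoms = ensemble$atoms, bonds = ensemble$bonds,
                 coords = ensemble$coords[[conformer]]),
            class = "molecule_3d")
}
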