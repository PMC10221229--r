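# SMILES handling backed by Open Babel (canonicalisation, validation) and
# the obabel command-line tool (fingerprints). All calls are batched: one
# conversion per dataset, not per molecule.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) abort("obabel was not found on the PATH.", class = "odorspace_missing_tool")
  p
}

#' Canonicalise SMILES strings
#'
#' Converts SMILES to Open Babel canonical form so that structurally
#' identical inputs compare equal regardless of their original atom
#' ordering or spelling. Unparsable entries are returned as `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of the same length; `NA` where the input did
#'   not parse to a molecule with at least one heavy atom.
#' @examples
#' canonical_smiles(c("OCC", "C(C)O", "not a molecule"))
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  convert <- function(payload) {
    suppressWarnings(suppressMessages(
      ChemmineOB::convertFormat("SMI", "CAN", payload)
    ))
  }
  payload <- paste0(trimws(smiles[idx]), " m", seq_along(idx), collapse = "\n")
  res <- convert(paste0(payload, "\n"))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    tag <- trimws(parts[2])
    can <- trimws(parts[1])
    i <- suppressWarnings(as.integer(sub("^m", "", tag)))
    if (!is.na(i) && nzchar(can)) out[idx[i]] <- can
  }
  # a parse error can abort the batch mid-stream: retry leftovers singly
  for (i in idx[is.na(out[idx])]) {
    res <- convert(paste0(trimws(smiles[i]), " one\n"))
    parts <- strsplit(res, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2L && nzchar(trimws(parts[1]))) {
      out[i] <- trimws(parts[1])
    }
  }
  out
}

# Parse one FPS hex line into a 0/1 integer vector.
fps_hex_to_bits <- function(hex) {
  nib <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  bits <- integer(length(nib) * 4L)
  for (b in 0:3) bits[seq_along(nib) * 4L - b] <- bitwAnd(nib, bitwShiftL(1L, b)) > 0
  as.integer(bits)
}

# Run obabel on a SMILES table and return the raw (unfolded) fingerprint
# matrix, rows aligned with the input ids.
obabel_fingerprints <- function(ids, smiles, fp_type) {
  smi_file <- tempfile(fileext = ".smi")
  on.exit(unlink(smi_file), add = TRUE)
  writeLines(paste(smiles, paste0("m", seq_along(ids))), smi_file)
  out <- suppressWarnings(system2(
    obabel_path(), c(smi_file, "-ofps", "-xf", fp_type),
    stdout = TRUE, stderr = FALSE
  ))
  out <- out[!startsWith(out, "#")]
  parts <- strsplit(out, "\t", fixed = TRUE)
  parts <- parts[lengths(parts) >= 2L]
  got <- vapply(parts, function(p) trimws(p[[2]]), character(1))
  hex <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  pos <- match(paste0("m", seq_along(ids)), got)
  if (anyNA(pos)) {
    abort(
      paste0("Fingerprint generation failed for: ",
             paste(ids[is.na(pos)], collapse = ", ")),
      class = "odorspace_chem_error"
    )
  }
  do.call(rbind, lapply(pos, function(i) fps_hex_to_bits(hex[i])))
}
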