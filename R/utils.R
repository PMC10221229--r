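# internal helpers shared across modules

#' @importFrom rlang abort warn inform %||%
NULL

# Deterministic 32-bit sub-seed derived from a base seed and a stage label,
# so each pipeline stage gets its own reproducible stream.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 31 + h * 2654435) %% .Machine$integer.max)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Normalize an odor-note string vector: lowercase, trim, collapse internal
# whitespace, split multi-word composites are NOT split here (see
# parse_notes for the delimiter handling).
normalize_notes <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  x[nzchar(x)]
}

# Split a delimited note field into a normalized, deduplicated note set.
# Space-separated composites such as "powdery orris" denote two notes and
# are split on whitespace after delimiter splitting.
parse_notes <- function(field, delimiter = ";") {
  if (is.na(field) || !nzchar(trimws(field))) return(character())
  raw <- unlist(strsplit(field, delimiter, fixed = TRUE))
  raw <- unlist(strsplit(trimws(raw), "\\s+"))
  unique(normalize_notes(raw))
}

pkg_file <- function(...) {
  system.file(..., package = "odorspace", mustWork = TRUE)
}
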