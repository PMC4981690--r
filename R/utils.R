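# Shared internal helpers: seeded evaluation, tabular I/O with a provenance
# header, and small argument checks used across the pipeline stages.

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

CLASS_LABELS <- c("A", "B", "C")

#' Run an expression with a fixed RNG seed
#'
#' Thin wrapper over [withr::with_seed()] so every stochastic stage of the
#' pipeline (generators, k-means restarts, network initialisation) is
#' reproducible and leaves the caller's RNG state untouched.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

assert_class_label <- function(x, arg = "class_label") {
  bad <- setdiff(unique(x), CLASS_LABELS)
  if (length(bad) > 0) {
    abort(sprintf("%s must be one of %s (got: %s)", arg,
                  paste(CLASS_LABELS, collapse = ", "),
                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Write a tibble as TSV with a provenance header
#'
#' Every table the pipeline writes carries a single `#`-prefixed header line
#' recording the package version, a hash of the generating configuration and
#' the seed, so artifacts can be traced to the run that produced them.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param seed Seed used by the generating stage (or `NA`).
#' @param config Arbitrary configuration object; hashed into the header.
#' @return `path`, invisibly.
#' @export
write_gh9_tsv <- function(x, path, seed = NA, config = NULL) {
  header <- sprintf("# gh9class %s\tconfig=%s\tseed=%s",
                    as.character(packageVersion("gh9class")),
                    rlang::hash(config), as.character(seed))
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by the pipeline
#'
#' @param path File path.
#' @return A tibble; header comment lines are skipped.
#' @export
read_gh9_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Tibble with at least `uid` and `residues` columns (as produced
#'   by [gen_families()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("uid", "residues") %in% names(seqs)))
  set <- Biostrings::AAStringSet(setNames(seqs$residues, seqs$uid))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Identifiers are the first whitespace-delimited token of each header.
#'
#' @param path FASTA path.
#' @return Tibble with `uid` and `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) abort(sprintf(
                    "could not parse FASTA '%s': %s", path, conditionMessage(e))))
  tibble(
    uid = vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L),
    residues = as.character(set)
  )
}

# middle order statistic of exactly three values (no interpolation)
median3 <- function(x) {
  stopifnot(length(x) == 3L)
  sort(x)[2L]
}
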