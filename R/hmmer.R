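# Wrappers around the HMMER3 command-line engine (hmmbuild / hmmsearch) and a
# small MAFFT helper. All profile construction and scoring is delegated to the
# engine; this file only marshals files and parses the domain table output.

hmmer_binary <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) abort(sprintf("HMMER binary '%s' not found on PATH", name))
  unname(path)
}

run_engine <- function(bin, args) {
  out <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    abort(sprintf("%s failed (exit %d):\n%s", bin, status,
                  paste(utils::tail(out, 15L), collapse = "\n")))
  }
  invisible(out)
}

#' Align protein sequences with MAFFT
#'
#' Two variants are exposed: the default progressive alignment (used for the
#' "1D" profile member) and the slower iterative local-pair refinement (used
#' for the "3D" member when no structure-derived alignment is supplied --
#' the 1D/3D distinction is metadata, and any aligned FASTA is accepted).
#'
#' @param seqs Tibble with `uid`, `residues`.
#' @param out Output aligned-FASTA path.
#' @param method `"default"` (FFT-NS-2) or `"localpair"` (L-INS-i).
#' @return `out`, invisibly.
#' @export
align_sequences <- function(seqs, out = tempfile(fileext = ".afa"),
                            method = c("default", "localpair")) {
  method <- match.arg(method)
  bin <- Sys.which("mafft")
  if (!nzchar(bin)) abort("mafft not found on PATH")
  faa <- tempfile(fileext = ".faa")
  on.exit(unlink(faa))
  write_fasta(seqs, faa)
  args <- c("--quiet", "--anysymbol",
            if (method == "localpair") c("--localpair", "--maxiterate", "100"),
            faa)
  aligned <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = FALSE))
  status <- attr(aligned, "status") %||% 0L
  if (status != 0L || length(aligned) == 0L) abort("mafft alignment failed")
  writeLines(aligned, out)
  invisible(out)
}

read_alignment <- function(path) {
  set <- Biostrings::readAAMultipleAlignment(path, format = "fasta")
  set
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Delegates construction to `hmmbuild`. The alignment must be an aligned
#' FASTA (or Stockholm) file with at least two rows of consistent width.
#'
#' @param alignment Path to the alignment file.
#' @param profile_id Model name recorded in the profile.
#' @param out Output `.hmm` path.
#' @param format Alignment format passed to `--informat`.
#' @param extra_args Additional `hmmbuild` arguments (e.g. `c("--ere", "0.45")`
#'   for a lower relative-entropy target).
#' @return Tibble row with `profile_id`, `hmm_path`, `model_length`.
#' @export
build_profile <- function(alignment, profile_id,
                          out = tempfile(fileext = ".hmm"),
                          format = c("afa", "stockholm"),
                          extra_args = character()) {
  format <- match.arg(format)
  if (!file.exists(alignment)) abort(sprintf("alignment not found: %s", alignment))
  aln <- tryCatch(
    read_alignment(alignment),
    error = function(e) abort(sprintf("unreadable/ragged alignment '%s': %s",
                                      alignment, conditionMessage(e)))
  )
  if (nrow(aln) < 2L) abort("alignment must have at least 2 rows")
  run_engine(hmmer_binary("hmmbuild"),
             c("--amino", "--informat", format, "-n", profile_id, extra_args,
               shQuote(out), shQuote(alignment)))
  tibble(profile_id = profile_id, hmm_path = out,
         model_length = hmm_model_length(out))
}

hmm_model_length <- function(hmm_path) {
  lines <- readLines(hmm_path, n = 30L)
  leng <- grep("^LENG", lines, value = TRUE)
  if (length(leng) == 0L) abort(sprintf("no LENG record in %s", hmm_path))
  as.integer(strsplit(leng[1], "\\s+")[[1]][2])
}

# Parse a --domtblout file into a long tibble. Fixed whitespace-delimited
# columns per the HMMER3 user guide; description field (>= col 23) ignored.
parse_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble(seq_id = character(), profile_id = character(),
                  seq_evalue = numeric(), seq_score = numeric(),
                  dom_ievalue = numeric(), dom_score = numeric()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  tibble(
    seq_id = map_chr(fields, 1L),
    profile_id = map_chr(fields, 4L),
    seq_evalue = as.numeric(map_chr(fields, 7L)),
    seq_score = as.numeric(map_chr(fields, 8L)),
    dom_ievalue = as.numeric(map_chr(fields, 13L)),
    dom_score = as.numeric(map_chr(fields, 14L))
  )
}

#' Search sequences with one or more profile HMMs
#'
#' Runs `hmmsearch` once over a concatenation of the given profiles and
#' returns all reported domains (one row per domain) at the requested
#' reporting thresholds.
#'
#' @param hmm_paths Character vector of `.hmm` files.
#' @param seq_path Protein FASTA of query sequences.
#' @param e_value Sequence- and domain-level reporting E-value threshold.
#' @return Long tibble: `seq_id`, `profile_id`, `seq_evalue`, `seq_score`,
#'   `dom_ievalue`, `dom_score`.
#' @export
hmm_search <- function(hmm_paths, seq_path, e_value = 1e-6) {
  stopifnot(length(hmm_paths) >= 1L, e_value > 0)
  missing <- hmm_paths[!file.exists(hmm_paths)]
  if (length(missing) > 0) {
    abort(sprintf("profile files not found: %s", paste(missing, collapse = ", ")))
  }
  if (!file.exists(seq_path)) abort(sprintf("FASTA not found: %s", seq_path))
  hmmdb <- tempfile(fileext = ".hmm")
  on.exit(unlink(hmmdb))
  file.create(hmmdb)
  for (p in hmm_paths) file.append(hmmdb, p)
  tbl <- tempfile(fileext = ".domtbl")
  on.exit(unlink(tbl), add = TRUE)
  run_engine(hmmer_binary("hmmsearch"),
             c("--noali", "-E", format(e_value, scientific = TRUE),
               "--domE", format(e_value, scientific = TRUE),
               "--domtblout", shQuote(tbl), shQuote(hmmdb), shQuote(seq_path)))
  parse_domtblout(tbl)
}
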