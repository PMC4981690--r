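# Scoring sequences against the registry and reducing the score table to
# class-pair members, class-mean triples and the maximum-mean class call.

#' Screen a proteome for putative homologs with the generic profiles
#'
#' Runs the generic (class X) 1D/3D pair against a proteome at the permissive
#' `e_generic` threshold and returns the deduplicated identifiers of all
#' sequences hit by either profile.
#'
#' @param seq_path Protein FASTA of the proteome.
#' @param registry A materialised [profile_registry()].
#' @param cfg A [search_config()].
#' @return Character vector of candidate sequence ids (possibly empty).
#' @export
screen_homologs <- function(seq_path, registry, cfg = search_config()) {
  stopifnot(inherits(registry, "gh9_registry"), inherits(cfg, "gh9_search_config"))
  generic <- dplyr::filter(as_tibble(registry), .data$scope == "generic")
  if (nrow(generic) == 0L || anyNA(generic$hmm_path)) {
    abort("registry has no materialised generic profiles")
  }
  seqs <- read_fasta(seq_path)
  if (nrow(seqs) == 0L) return(character())
  hits <- hmm_search(generic$hmm_path, seq_path, e_value = cfg$e_generic)
  unique(hits$seq_id[hits$seq_evalue <= cfg$e_generic])
}

#' Score sequences against every class and leave-one-out profile
#'
#' One `hmmsearch` pass over the concatenated class/leave-one-out profile
#' database. Each cell of the returned table is the best single-region
#' (domain) bit score for that sequence/profile pair -- or the full-sequence
#' score when `cfg$score_kind = "full_sequence"` -- and `NA` when the engine
#' reported no hit at the `e_class` threshold.
#'
#' @param seqs Tibble with `uid`, `residues`, or a FASTA path.
#' @param registry A materialised [profile_registry()].
#' @param cfg A [search_config()].
#' @return Wide tibble: `seq_id` plus one numeric column per class/loocv
#'   profile id.
#' @export
score_profiles <- function(seqs, registry, cfg = search_config()) {
  stopifnot(inherits(registry, "gh9_registry"), inherits(cfg, "gh9_search_config"))
  profs <- dplyr::filter(as_tibble(registry), .data$scope != "generic")
  if (nrow(profs) == 0L) abort("registry has no class/leave-one-out profiles")
  if (anyNA(profs$hmm_path)) abort("registry profiles are not materialised; run build_registry_profiles()")
  if (is.character(seqs) && length(seqs) == 1L) {
    seq_path <- seqs
    seqs <- read_fasta(seq_path)
  } else {
    seq_path <- tempfile(fileext = ".faa")
    on.exit(unlink(seq_path))
    write_fasta(seqs, seq_path)
  }
  hits <- hmm_search(profs$hmm_path, seq_path, e_value = cfg$e_class)
  best <- hits |>
    group_by(.data$seq_id, .data$profile_id) |>
    summarise(score = if (cfg$score_kind == "best_domain") max(.data$dom_score)
              else max(.data$seq_score), .groups = "drop")
  wide <- tidyr::pivot_wider(best, names_from = "profile_id", values_from = "score")
  # one row per input sequence, one column per profile, in registry order
  out <- tibble(seq_id = seqs$uid) |> left_join(wide, by = "seq_id")
  for (p in setdiff(profs$profile_id, names(out))) out[[p]] <- NA_real_
  out[, c("seq_id", profs$profile_id)]
}

# mean over contributing profile scores with the documented missing-cell
# policy: NA -> 0 (warning) when the class has at least one real hit; all-NA
# classes are degenerate and flagged.
member_mean <- function(scores, seq_id, class_label) {
  if (length(scores) == 0L || all(is.na(scores))) return(NA_real_)
  if (anyNA(scores)) {
    warn(sprintf("sequence %s: %d missing class-%s profile score(s) treated as 0 bits",
                 seq_id, sum(is.na(scores)), class_label))
    scores[is.na(scores)] <- 0
  }
  mean(scores)
}

#' Reduce a score table to class-pair members
#'
#' For every sequence, each class contributes a two-member group: the mean of
#' its 1D-side profile scores and the mean of its 3D-side profile scores. In
#' generic mode these are the class-level 1D/3D pair scores themselves; in
#' leave-one-out mode they pool the retained profiles of
#' [select_loocv()] for that training sequence.
#'
#' Missing cells are zeroed with a warning when the class has at least one
#' real hit; a class with no hits at all leaves the sequence flagged
#' `unclassifiable`.
#'
#' @param scores Wide score table from [score_profiles()].
#' @param registry The [profile_registry()] the scores were computed with.
#' @param mode `"generic"` or `"loocv"`.
#' @return Tibble with `seq_id`, member columns `a_1d` .. `c_3d` (bits) and an
#'   `unclassifiable` flag.
#' @export
score_members <- function(scores, registry, mode = c("generic", "loocv")) {
  mode <- match.arg(mode)
  stopifnot(inherits(registry, "gh9_registry"))
  reg <- as_tibble(registry)
  rows <- purrr::map(seq_len(nrow(scores)), function(i) {
    seq_id <- scores$seq_id[i]
    if (mode == "loocv") {
      sel <- select_loocv(registry, seq_id)
      pool <- dplyr::filter(reg, .data$profile_id %in% sel$retained_profile_ids)
    } else {
      pool <- dplyr::filter(reg, .data$scope == "class")
    }
    members <- purrr::map(CLASS_LABELS, function(cl) {
      purrr::map_dbl(REP_LEVELS, function(rp) {
        ids <- pool$profile_id[pool$class_label == cl & pool$rep == rp]
        ids <- intersect(ids, names(scores))
        member_mean(unlist(scores[i, ids], use.names = FALSE), seq_id, cl)
      })
    })
    tibble(seq_id = seq_id,
           a_1d = members[[1]][1], a_3d = members[[1]][2],
           b_1d = members[[2]][1], b_3d = members[[2]][2],
           c_1d = members[[3]][1], c_3d = members[[3]][2])
  }) |> dplyr::bind_rows()
  rows$unclassifiable <- !stats::complete.cases(
    rows[, c("a_1d", "a_3d", "b_1d", "b_3d", "c_1d", "c_3d")])
  if (any(rows$unclassifiable)) {
    warn(sprintf("%d sequence(s) have an entire class without hits and are unclassifiable",
                 sum(rows$unclassifiable)))
  }
  rows
}

#' Class-mean triple from class-pair members
#'
#' Each class mean is the arithmetic mean of the class's 1D-side and 3D-side
#' member scores.
#'
#' @param members Tibble from [score_members()] (or with the same six member
#'   columns, e.g. [gen_score_table()]).
#' @return `members` with `hmm_a`, `hmm_b`, `hmm_c` columns appended.
#' @export
class_means <- function(members) {
  need <- c("a_1d", "a_3d", "b_1d", "b_3d", "c_1d", "c_3d")
  stopifnot(all(need %in% names(members)))
  members |>
    mutate(hmm_a = (.data$a_1d + .data$a_3d) / 2,
           hmm_b = (.data$b_1d + .data$b_3d) / 2,
           hmm_c = (.data$c_1d + .data$c_3d) / 2)
}

#' Maximum-mean class call
#'
#' The inferred enzyme class of a sequence is the label of the strictly
#' largest class mean; exact ties are flagged `"ambiguous"` rather than broken
#' silently (the screening filter exists precisely to remove near-ties).
#'
#' @param hmm_a,hmm_b,hmm_c Numeric vectors of class means (bits).
#' @return Character vector over `{"A","B","C","ambiguous"}` (`NA` in, `NA` out).
#' @export
#' @examples
#' max_class(300, 250, 200)  # "A"
#' max_class(100, 200, 200)  # "ambiguous"
max_class <- function(hmm_a, hmm_b, hmm_c) {
  m <- cbind(hmm_a, hmm_b, hmm_c)
  apply(m, 1L, function(r) {
    if (anyNA(r)) return(NA_character_)
    top <- which(r == max(r))
    if (length(top) > 1L) "ambiguous" else CLASS_LABELS[top]
  })
}
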