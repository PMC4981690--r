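# The profile registry: metadata for generic, class-level and leave-one-out
# profiles (1D and 3D variants), plus the leave-one-out selection rule and the
# delta fraction of class-specific profiles it retains.

REP_LEVELS <- c("1D", "3D")

#' Search/reporting configuration
#'
#' @param e_class Reporting E-value for class and leave-one-out profiles
#'   (default `1e-6`; the generic homolog screen is seven orders of magnitude
#'   more permissive).
#' @param e_generic Reporting E-value for the generic homolog screen
#'   (default `10`).
#' @param score_kind `"best_domain"` (the highest-scoring single region, the
#'   default) or `"full_sequence"`.
#' @return A `gh9_search_config` list.
#' @export
search_config <- function(e_class = 1e-6, e_generic = 10,
                          score_kind = c("best_domain", "full_sequence")) {
  score_kind <- match.arg(score_kind)
  if (e_class <= 0 || e_generic <= 0) abort("E-value thresholds must be > 0")
  if (e_class >= e_generic) abort("e_class must be below e_generic")
  structure(list(e_class = e_class, e_generic = e_generic,
                 score_kind = score_kind),
            class = "gh9_search_config")
}

#' Build the profile registry metadata for a training set
#'
#' For training counts `n = (n_A, n_B, n_C)` the registry holds one generic
#' (class X) 1D/3D pair, one 1D/3D pair per class, and, for every training
#' sequence, a 1D/3D leave-one-out pair excluding it: `2 * n_class` leave-one-out
#' profiles per class. Profiles are metadata-only until
#' [build_registry_profiles()] attaches engine-built models.
#'
#' @param train_meta Tibble with `uid` and `class_label` (A/B/C) for every
#'   training sequence.
#' @return A `gh9_registry` tibble: `profile_id`, `scope` (generic / class /
#'   loocv), `class_label` (X/A/B/C), `rep` (1D/3D), `excluded_uid`,
#'   `hmm_path`, `model_length`.
#' @export
#' @examples
#' meta <- tibble::tibble(
#'   uid = sprintf("U%02d", 1:26),
#'   class_label = rep(c("A", "B", "C"), c(6, 16, 4))
#' )
#' reg <- profile_registry(meta)
#' dplyr::count(reg, scope, class_label)
profile_registry <- function(train_meta) {
  stopifnot(all(c("uid", "class_label") %in% names(train_meta)))
  assert_class_label(train_meta$class_label)
  if (anyDuplicated(train_meta$uid)) abort("training uids must be unique")
  counts <- table(factor(train_meta$class_label, CLASS_LABELS))
  if (any(counts < 2L)) {
    abort(sprintf(
      "leave-one-out profiles are undefined for classes with < 2 sequences (counts: %s)",
      paste(sprintf("%s=%d", CLASS_LABELS, counts), collapse = ", ")))
  }
  generic <- tibble(profile_id = paste0("HMMX_", REP_LEVELS), scope = "generic",
                    class_label = "X", rep = REP_LEVELS, excluded_uid = NA_character_)
  class_level <- purrr::map(CLASS_LABELS, function(cl) {
    tibble(profile_id = paste0("HMM", cl, "_", REP_LEVELS), scope = "class",
           class_label = cl, rep = REP_LEVELS, excluded_uid = NA_character_)
  }) |> dplyr::bind_rows()
  loocv <- purrr::pmap(train_meta[, c("uid", "class_label")], function(uid, class_label) {
    tibble(profile_id = sprintf("HMM%s_loo_%s_%s", class_label, uid, REP_LEVELS),
           scope = "loocv", class_label = class_label, rep = REP_LEVELS,
           excluded_uid = uid)
  }) |> dplyr::bind_rows()
  out <- dplyr::bind_rows(generic, class_level, loocv) |>
    mutate(hmm_path = NA_character_, model_length = NA_integer_)
  class(out) <- c("gh9_registry", class(out))
  out
}

#' Count profiles per scope and class
#'
#' @param registry A [profile_registry()].
#' @return Tibble of counts per `(scope, class_label)`.
#' @export
registry_counts <- function(registry) {
  dplyr::count(as_tibble(registry), .data$scope, .data$class_label)
}

#' Build engine profiles for every registry entry
#'
#' Aligns the appropriate training subset for each profile (all sequences for
#' generic, the class members for class-level, the class members minus the
#' excluded sequence for leave-one-out) and runs `hmmbuild`. The "1D" member
#' uses the default progressive alignment and the "3D" member the iterative
#' local-pair alignment unless explicit alignment files are supplied via
#' `alignments`.
#'
#' When no external "3D" alignment is supplied, the 3D member is additionally
#' built with a lower relative-entropy target (`--ere ere_3d`), so the two
#' members of a profile pair are genuinely different models of the same
#' subset. This emulates the systematic bit-score offset between sequence- and
#' structure-derived profiles, which is what gives the per-class score groups
#' their non-degenerate within-group variance.
#'
#' @param registry A [profile_registry()].
#' @param train_seqs Tibble with `uid`, `class_label`, `residues` for the full
#'   training set.
#' @param out_dir Directory receiving `.hmm` files (created if needed).
#' @param alignments Optional named character vector mapping `profile_id` to a
#'   pre-computed aligned-FASTA path (e.g. genuine structure-derived
#'   alignments); profiles not named fall back to the MAFFT helper.
#' @param ere_3d Relative-entropy target for helper-aligned 3D members; `NULL`
#'   to disable.
#' @return The registry with `hmm_path` and `model_length` filled in.
#' @export
build_registry_profiles <- function(registry, train_seqs, out_dir = tempfile("registry_"),
                                    alignments = NULL, ere_3d = 0.45) {
  stopifnot(inherits(registry, "gh9_registry"))
  stopifnot(all(c("uid", "class_label", "residues") %in% names(train_seqs)))
  missing_uid <- setdiff(stats::na.omit(registry$excluded_uid), train_seqs$uid)
  if (length(missing_uid) > 0) {
    abort(sprintf("registry references training uids absent from train_seqs: %s",
                  paste(missing_uid, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # alignments are shared between the 1D/3D pair members of the same subset,
  # but computed with different aligners so the pair scores are not identical
  aln_cache <- new.env(parent = emptyenv())
  subset_alignment <- function(subset, key, method) {
    cache_key <- paste(key, method, sep = "|")
    if (!is.null(aln_cache[[cache_key]])) return(aln_cache[[cache_key]])
    path <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_]", "_", cache_key), ".afa"))
    align_sequences(subset, path, method = method)
    aln_cache[[cache_key]] <- path
    path
  }
  built <- purrr::pmap(registry, function(profile_id, scope, class_label, rep,
                                          excluded_uid, hmm_path, model_length) {
    subset <- switch(scope,
      generic = train_seqs,
      class = dplyr::filter(train_seqs, .data$class_label == !!class_label),
      loocv = dplyr::filter(train_seqs, .data$class_label == !!class_label,
                            .data$uid != excluded_uid)
    )
    if (nrow(subset) < 2L) {
      abort(sprintf("profile %s: alignment subset has < 2 sequences", profile_id))
    }
    extra <- character()
    if (!is.null(alignments) && profile_id %in% names(alignments)) {
      aln <- alignments[[profile_id]]
    } else {
      key <- paste(scope, class_label, excluded_uid %||% "", sep = "_")
      aln <- subset_alignment(subset, key,
                              method = if (rep == "3D") "localpair" else "default")
      if (rep == "3D" && !is.null(ere_3d)) extra <- c("--ere", format(ere_3d))
    }
    build_profile(aln, profile_id, out = file.path(out_dir, paste0(profile_id, ".hmm")),
                  extra_args = extra)
  }) |> dplyr::bind_rows()
  out <- registry |>
    select(-"hmm_path", -"model_length") |>
    left_join(built, by = "profile_id")
  class(out) <- c("gh9_registry", class(out))
  out
}

#' Build a fully materialised leave-one-out registry
#'
#' Convenience wrapper: [profile_registry()] + [build_registry_profiles()].
#'
#' @inheritParams build_registry_profiles
#' @return A `gh9_registry` with engine profiles attached.
#' @export
build_loocv_registry <- function(train_seqs, out_dir = tempfile("registry_"),
                                 alignments = NULL, ere_3d = 0.45) {
  registry <- profile_registry(train_seqs[, c("uid", "class_label")])
  build_registry_profiles(registry, train_seqs, out_dir, alignments, ere_3d)
}

#' Leave-one-out profile selection for a training sequence
#'
#' For a target of class X, all leave-one-out profiles of the two other
#' classes are retained plus the single 1D/3D pair of class X whose excluded
#' sequence is the target itself (the only class-X leave-one-out profiles that
#' never saw the target in their alignment). The delta fraction divides the
#' retained count by the total number of class-specific profiles (all
#' leave-one-out profiles plus the six class-level profiles).
#'
#' @param registry A [profile_registry()].
#' @param target_uid Accession of the training sequence.
#' @return A `gh9_loocv_selection` list: `target_uid`, `target_class`,
#'   `retained_profile_ids`, `delta_fraction`.
#' @export
#' @examples
#' meta <- tibble::tibble(
#'   uid = sprintf("U%02d", 1:26),
#'   class_label = rep(c("A", "B", "C"), c(6, 16, 4))
#' )
#' sel <- select_loocv(profile_registry(meta), "U01")
#' length(sel$retained_profile_ids)  # 42
#' round(sel$delta_fraction, 2)      # 0.72
select_loocv <- function(registry, target_uid) {
  stopifnot(inherits(registry, "gh9_registry"))
  loocv <- dplyr::filter(as_tibble(registry), .data$scope == "loocv")
  hit <- dplyr::filter(loocv, .data$excluded_uid == target_uid)
  if (nrow(hit) == 0L) {
    abort(sprintf("no leave-one-out profiles exclude uid '%s'", target_uid))
  }
  target_class <- unique(hit$class_label)
  retained <- dplyr::filter(loocv, .data$class_label != target_class |
                              .data$excluded_uid == target_uid)
  n_class_specific <- nrow(loocv) + sum(registry$scope == "class")
  structure(
    list(target_uid = target_uid, target_class = target_class,
         retained_profile_ids = retained$profile_id,
         delta_fraction = nrow(retained) / n_class_specific),
    class = "gh9_loocv_selection"
  )
}

#' @export
print.gh9_loocv_selection <- function(x, ...) {
  cat(sprintf("<leave-one-out selection> target %s (class %s): %d profiles retained, delta = %.4f\n",
              x$target_uid, x$target_class, length(x$retained_profile_ids),
              x$delta_fraction))
  invisible(x)
}
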