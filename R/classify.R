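# Final class assignment: the interval rule table on (beta'', alpha13), its
# YAML representation and disjointness validation, derivation of interval
# bounds from a calibration run, precision/recall evaluation and per-organism
# taxonomy summaries.

#' The default assignment rule table
#'
#' Interval rules on the network prediction beta'' with an alpha13 side
#' condition disambiguating the band where classes A and C overlap:
#' * A: `9.95 < beta'' < 10.779` and `alpha13 < 0.02`
#' * B (high confidence): `3.45 < beta'' < 5.55`
#' * B (low confidence): `5.55 <= beta'' < 8.2052`
#' * C: `8.2052 <= beta'' <= 9.95`, or `9.95 < beta'' < 10.779` with
#'   `alpha13 > 0.02`, or `10.779 <= beta'' <= 11.371`
#'
#' Values outside every interval -- including `alpha13 = 0.02` exactly inside
#' the contested band -- are `unassigned`; the rules are never silently
#' extended.
#'
#' @return A `gh9_rules` tibble: `label`, `lo`, `hi`, `lo_open`, `hi_open`,
#'   `alpha13_op` (`"<"`, `">"`, or `NA`), `alpha13_value`.
#' @export
default_rules <- function() {
  rules <- tibble(
    label = c("A", "B_high", "B_low", "C", "C", "C"),
    lo = c(9.95, 3.45, 5.55, 8.2052, 9.95, 10.779),
    hi = c(10.779, 5.55, 8.2052, 9.95, 10.779, 11.371),
    lo_open = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    hi_open = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    alpha13_op = c("<", NA, NA, NA, ">", NA),
    alpha13_value = c(0.02, NA, NA, NA, 0.02, NA)
  )
  validate_rules(rules)
}

#' Validate a rule table
#'
#' Checks interval non-emptiness and disjointness: no two rules with different
#' labels may match the same `(beta'', alpha13)` point. Disjointness is
#' verified by a dense grid scan over the spanned beta'' range crossed with
#' alpha13 values around every rule's side condition.
#'
#' @param rules A rule tibble (see [default_rules()]).
#' @param grid_n Number of beta'' grid points.
#' @return The validated rules, classed `gh9_rules`.
#' @export
validate_rules <- function(rules, grid_n = 4001L) {
  need <- c("label", "lo", "hi", "lo_open", "hi_open", "alpha13_op", "alpha13_value")
  stopifnot(all(need %in% names(rules)))
  if (any(rules$lo > rules$hi) ||
      any(rules$lo == rules$hi & (rules$lo_open | rules$hi_open))) {
    abort("rule table contains an empty interval")
  }
  span <- range(c(rules$lo, rules$hi))
  pad <- diff(span) * 0.05 + 1e-6
  beta_grid <- seq(span[1] - pad, span[2] + pad, length.out = grid_n)
  beta_grid <- sort(c(beta_grid, rules$lo, rules$hi))  # include the boundaries
  a13_grid <- sort(unique(c(0, as.vector(
    outer(stats::na.omit(rules$alpha13_value), c(0.5, 1, 1.5))))))
  for (a13 in a13_grid) {
    labels <- match_rules(beta_grid, a13, rules)
    multi <- labels$n_labels > 1L
    if (any(multi)) {
      abort(sprintf("overlapping rules: beta''=%.6g, alpha13=%.3g matches %s",
                    beta_grid[which(multi)[1]], a13,
                    labels$all_labels[which(multi)[1]]))
    }
  }
  class(rules) <- unique(c("gh9_rules", class(rules)))
  rules
}

# which distinct labels match each beta'' value at a fixed alpha13
match_rules <- function(beta_pp, alpha13, rules) {
  hit_labels <- purrr::map(seq_along(beta_pp), function(i) {
    b <- beta_pp[i]
    a <- if (length(alpha13) == 1L) alpha13 else alpha13[i]
    ok <- purrr::map_lgl(seq_len(nrow(rules)), function(r) {
      lo_ok <- if (rules$lo_open[r]) b > rules$lo[r] else b >= rules$lo[r]
      hi_ok <- if (rules$hi_open[r]) b < rules$hi[r] else b <= rules$hi[r]
      side <- if (is.na(rules$alpha13_op[r])) TRUE else {
        if (is.na(a)) FALSE
        else if (rules$alpha13_op[r] == "<") a < rules$alpha13_value[r]
        else a > rules$alpha13_value[r]
      }
      lo_ok && hi_ok && side
    })
    unique(rules$label[ok])
  })
  tibble(
    n_labels = lengths(hit_labels),
    label = purrr::map_chr(hit_labels, ~ if (length(.x) == 1L) .x else NA_character_),
    all_labels = purrr::map_chr(hit_labels, paste, collapse = "+")
  )
}

#' Assign classes from network predictions
#'
#' Applies the rule table to each `(beta'', alpha13)` pair. The confidence
#' column renders `B_high` as `"B+"` and `B_low` as `"B-"`.
#'
#' @param data Tibble with `seq_id`, `beta_pp`, `alpha13` (and optionally
#'   `well_spaced`, carried through).
#' @param rules A validated rule table (default [default_rules()]).
#' @return Tibble with `label` (`A`, `B_high`, `B_low`, `C`, `unassigned`) and
#'   `confidence` appended.
#' @export
#' @examples
#' assign_class(tibble::tibble(seq_id = "s1", beta_pp = 9.0, alpha13 = 0))$label  # "C"
assign_class <- function(data, rules = default_rules()) {
  stopifnot(all(c("seq_id", "beta_pp", "alpha13") %in% names(data)))
  if (!inherits(rules, "gh9_rules")) rules <- validate_rules(rules)
  m <- match_rules(data$beta_pp, data$alpha13, rules)
  out <- data |>
    mutate(label = dplyr::coalesce(m$label, "unassigned"),
           confidence = dplyr::case_when(
             .data$label == "B_high" ~ "B+",
             .data$label == "B_low" ~ "B-",
             .data$label == "unassigned" ~ NA_character_,
             TRUE ~ .data$label
           ))
  out
}

#' Derive interval rules from a calibration run
#'
#' Computes per-class closed `[min, max]` intervals of beta'' from a
#' calibration set with reference labels (the maximum-mean profile class of
#' each sequence). Class B is rendered as a single high-confidence interval.
#' Overlapping derived intervals fail validation, as they must.
#'
#' @param beta_pp Numeric vector of network predictions.
#' @param reference Character vector of reference labels (A/B/C).
#' @return A validated `gh9_rules` tibble.
#' @export
derive_rules <- function(beta_pp, reference) {
  assert_class_label(reference)
  keep <- !is.na(beta_pp) & !is.na(reference)
  d <- tibble(beta_pp = beta_pp[keep], reference = reference[keep]) |>
    group_by(.data$reference) |>
    summarise(lo = min(.data$beta_pp), hi = max(.data$beta_pp), .groups = "drop")
  rules <- tibble(
    label = ifelse(d$reference == "B", "B_high", d$reference),
    lo = d$lo, hi = d$hi,
    lo_open = FALSE, hi_open = FALSE,
    alpha13_op = NA_character_, alpha13_value = NA_real_
  )
  validate_rules(rules)
}

#' Read / write a rule table as YAML
#'
#' @param path YAML file path.
#' @param rules A rule tibble.
#' @return `read_rules_yaml()` returns a validated `gh9_rules` tibble;
#'   `write_rules_yaml()` returns `path` invisibly.
#' @export
read_rules_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- purrr::map(raw, function(r) {
    tibble(label = r$label, lo = r$lo, hi = r$hi,
           lo_open = isTRUE(r$lo_open), hi_open = isTRUE(r$hi_open),
           alpha13_op = if (is.null(r$alpha13)) NA_character_ else r$alpha13$op,
           alpha13_value = if (is.null(r$alpha13)) NA_real_ else r$alpha13$value)
  }) |> dplyr::bind_rows()
  validate_rules(rules)
}

#' @rdname read_rules_yaml
#' @export
write_rules_yaml <- function(rules, path) {
  items <- purrr::map(seq_len(nrow(rules)), function(i) {
    r <- as.list(rules[i, ])
    out <- list(label = r$label, lo = r$lo, hi = r$hi,
                lo_open = r$lo_open, hi_open = r$hi_open)
    out$alpha13 <- if (is.na(r$alpha13_op)) NULL else
      list(op = r$alpha13_op, value = r$alpha13_value)
    out
  })
  yaml::write_yaml(items, path)
  invisible(path)
}

#' Evaluate assignments against reference labels per screening partition
#'
#' Per partition: `M` = assigned label (B confidence levels collapsed to B)
#' agrees with the reference label; `MM` = disagrees; `NM` = unassigned.
#' Precision is `M / n_seq` within the partition and recall is `M` over the
#' total matches across partitions. When the inter-profile deltas are
#' supplied, their pooled per-partition median and mean (over the 3 deltas of
#' each matched sequence) are reported alongside.
#'
#' @param assignments Tibble with `seq_id`, `label`.
#' @param reference Tibble with `seq_id`, `reference` (A/B/C).
#' @param partitions Tibble with `seq_id`, `partition`, and optionally
#'   `d_ab`, `d_bc`, `d_ac`.
#' @return A `gh9_eval` tibble: one row per partition with `n_seq`, `M`, `MM`,
#'   `NM`, `precision`, `recall`, `delta_median`, `delta_mean`, `n_deltas`.
#' @export
evaluate_assignments <- function(assignments, reference, partitions) {
  stopifnot(all(c("seq_id", "label") %in% names(assignments)),
            all(c("seq_id", "reference") %in% names(reference)),
            all(c("seq_id", "partition") %in% names(partitions)))
  joined <- assignments |>
    left_join(reference, by = "seq_id") |>
    left_join(partitions, by = "seq_id")
  if (anyNA(joined$reference) || anyNA(joined$partition)) {
    abort("every assignment needs a reference label and a partition")
  }
  joined <- joined |>
    mutate(collapsed = dplyr::recode(.data$label, B_high = "B", B_low = "B"),
           outcome = dplyr::case_when(
             .data$collapsed == "unassigned" ~ "NM",
             .data$collapsed == .data$reference ~ "M",
             TRUE ~ "MM"
           ))
  has_deltas <- all(c("d_ab", "d_bc", "d_ac") %in% names(joined))
  out <- joined |>
    group_by(.data$partition) |>
    summarise(
      n_seq = dplyr::n(),
      M = sum(.data$outcome == "M"),
      MM = sum(.data$outcome == "MM"),
      NM = sum(.data$outcome == "NM"),
      delta_median = if (has_deltas) {
        v <- c(.data$d_ab[.data$outcome == "M"], .data$d_bc[.data$outcome == "M"],
               .data$d_ac[.data$outcome == "M"])
        if (length(v)) median(v) else NA_real_
      } else NA_real_,
      delta_mean = if (has_deltas) {
        v <- c(.data$d_ab[.data$outcome == "M"], .data$d_bc[.data$outcome == "M"],
               .data$d_ac[.data$outcome == "M"])
        if (length(v)) mean(v) else NA_real_
      } else NA_real_,
      n_deltas = 3L * sum(.data$outcome == "M"),
      .groups = "drop"
    ) |>
    mutate(precision = .data$M / .data$n_seq,
           recall = if (sum(.data$M) > 0) .data$M / sum(.data$M) else NA_real_)
  class(out) <- c("gh9_eval", class(out))
  out
}

#' Per-organism class counts
#'
#' Summarises assignments per organism: counts of classes A, B (high and low
#' confidence) and C, and the total number of sequences passing the beta
#' screen (when a `well_spaced` or `partition` column is available, the total
#' counts partition-`AA` sequences, else all assigned sequences).
#'
#' @param assignments Tibble with `organism`, `label`, and optionally
#'   `partition`.
#' @return Tibble: `organism`, `A`, `B_high`, `B_low`, `C`, `total`.
#' @export
summarize_taxonomy <- function(assignments) {
  stopifnot(all(c("organism", "label") %in% names(assignments)))
  if (nrow(assignments) == 0L) {
    return(tibble(organism = character(), A = integer(), B_high = integer(),
                  B_low = integer(), C = integer(), total = integer()))
  }
  passing <- if ("partition" %in% names(assignments)) {
    assignments$partition == "AA"
  } else {
    assignments$label != "unassigned"
  }
  assignments |>
    mutate(.pass = passing) |>
    group_by(.data$organism) |>
    summarise(
      A = sum(.data$label == "A"),
      B_high = sum(.data$label == "B_high"),
      B_low = sum(.data$label == "B_low"),
      C = sum(.data$label == "C"),
      total = sum(.data$.pass),
      .groups = "drop"
    )
}
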