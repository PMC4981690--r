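# The modified z-score disambiguation statistic: per-class group statistics,
# the pairwise alpha terms, their sum beta, the inter-profile score deltas and
# the screening partition.

#' Screening thresholds
#'
#' @param beta_hi Upper beta threshold: sequences with `beta > beta_hi` pass
#'   (partition `AA`). Default 2.777.
#' @param beta_lo Lower beta threshold: `beta < beta_lo` fails (partition
#'   `AC`); the closed interval between the two is intermediate (`AB`).
#'   Default 1.00.
#' @param delta_min Minimum median inter-profile score difference (bits) for a
#'   sequence to count as well spaced. Default 200.
#' @return A `gh9_screen_config` list.
#' @export
screen_config <- function(beta_hi = 2.777, beta_lo = 1.00, delta_min = 200) {
  if (beta_lo >= beta_hi) abort("beta_lo must be below beta_hi")
  if (delta_min < 0) abort("delta_min must be >= 0")
  structure(list(beta_hi = beta_hi, beta_lo = beta_lo, delta_min = delta_min),
            class = "gh9_screen_config")
}

#' Intra-group statistics of a two-member score group
#'
#' Each class contributes a group of exactly two members (its 1D-side and
#' 3D-side mean scores); the group is exhaustive, so the population variance
#' (divide by the member count tau = 2) is used by default.
#'
#' @param members Numeric vector of exactly two finite scores (bits).
#' @param variance `"population"` (default) or `"sample"`.
#' @return A `gh9_group` list: `mu`, `sigma2`, `tau`, `members`.
#' @export
#' @examples
#' group_stats(c(100, 110))  # mu 105, sigma2 25
group_stats <- function(members, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (length(members) != 2L || !all(is.finite(members))) {
    abort("a score group must have exactly two finite members")
  }
  mu <- mean(members)
  sigma2 <- sum((members - mu)^2) / if (variance == "population") 2 else 1
  structure(list(mu = mu, sigma2 = sigma2, tau = 2L, members = members),
            class = "gh9_group")
}

#' Pairwise alpha statistic between two score groups
#'
#' The dimensionless separation term
#' \deqn{\alpha_{ij} = \frac{\tau^2 (\mu_i - \mu_j)^2}{100 (\sigma_i^2 + \sigma_j^2)}}
#' i.e. one hundredth of the squared inter-group z-score with the pooled
#' standard error \eqn{\sqrt{(\sigma_i^2+\sigma_j^2)}/\tau}. A variant
#' parenthesization (`formula = "eq2"`) is exposed for sensitivity checks:
#' it divides by the squared pooled variance term instead,
#' \eqn{|\mu_i-\mu_j|^2 / (100 (\sigma_i^2 + \sigma_j^2/\tau)^2)}.
#'
#' When both variances vanish but the means differ, the denominator is floored
#' at `eps` and the result flagged saturated instead of overflowing.
#'
#' @param gi,gj [group_stats()] objects (tau = 2 each).
#' @param formula `"tau_sq"` (default) or `"eq2"`.
#' @param eps Zero-variance floor for the denominator (bits^2).
#' @return A `gh9_alpha` list: `alpha`, `z` (diagnostic inter-group z-score),
#'   `saturated`.
#' @export
#' @examples
#' alpha_stat(group_stats(c(100, 110)), group_stats(c(200, 220)))
alpha_stat <- function(gi, gj, formula = c("tau_sq", "eq2"), eps = 1e-9) {
  formula <- match.arg(formula)
  stopifnot(inherits(gi, "gh9_group"), inherits(gj, "gh9_group"))
  if (gi$tau != 2L || gj$tau != 2L) abort("alpha is defined for two-member groups")
  d <- abs(gi$mu - gj$mu)
  pooled <- gi$sigma2 + gj$sigma2
  saturated <- FALSE
  denom_var <- pooled
  if (denom_var < eps && d > 0) {
    denom_var <- eps
    saturated <- TRUE
  }
  denom_eq2 <- (gi$sigma2 + gj$sigma2 / gi$tau)^2
  if (formula == "eq2" && denom_eq2 < eps && d > 0) {
    denom_eq2 <- eps
    saturated <- TRUE
  }
  alpha <- if (d == 0) {
    0
  } else if (formula == "tau_sq") {
    (gi$tau^2 * d^2) / (100 * denom_var)
  } else {
    d^2 / (100 * denom_eq2)
  }
  z <- if (d == 0) 0 else d / sqrt(denom_var / gi$tau)
  structure(list(alpha = alpha, z = z, saturated = saturated),
            class = "gh9_alpha")
}

#' Beta disambiguation score from an alpha triple
#'
#' Beta is half the symmetric 3x3 double sum of the pairwise alphas over
#' distinct indices -- i.e. simply `a12 + a23 + a13`.
#'
#' @param a12,a23,a13 Pairwise alpha values (vectorised).
#' @return Numeric vector of beta values.
#' @export
beta_stat <- function(a12, a23, a13) {
  a12 + a23 + a13
}

#' Pairwise inter-profile score differences and their median
#'
#' @param hmm_a,hmm_b,hmm_c Class means (bits), vectorised.
#' @return Tibble with `d_ab`, `d_bc`, `d_ac` (absolute differences, bits) and
#'   `median_delta` (middle order statistic, no interpolation).
#' @export
#' @examples
#' delta_hmm(500, 300, 100)  # deltas 200/200/400, median 200
delta_hmm <- function(hmm_a, hmm_b, hmm_c) {
  d_ab <- abs(hmm_a - hmm_b)
  d_bc <- abs(hmm_b - hmm_c)
  d_ac <- abs(hmm_a - hmm_c)
  tibble(d_ab = d_ab, d_bc = d_bc, d_ac = d_ac,
         median_delta = purrr::pmap_dbl(list(d_ab, d_bc, d_ac),
                                        function(...) median3(c(...))))
}

#' Screening partition of a beta value
#'
#' `AA` (pass) when `beta > beta_hi`; `AB` (intermediate) when
#' `beta_lo <= beta <= beta_hi`; `AC` (fail) below `beta_lo`.
#'
#' @param beta Numeric vector of beta values.
#' @param cfg A [screen_config()].
#' @return Character vector over `{"AA","AB","AC"}`.
#' @export
screen_partition <- function(beta, cfg = screen_config()) {
  stopifnot(inherits(cfg, "gh9_screen_config"))
  dplyr::case_when(
    beta > cfg$beta_hi ~ "AA",
    beta >= cfg$beta_lo ~ "AB",
    TRUE ~ "AC"
  )
}

#' Compute the full beta table for a set of sequences
#'
#' Takes the six class-pair member scores per sequence (from
#' [score_members()] or [gen_score_table()]) and returns the class means,
#' pairwise alphas and diagnostic z-scores, beta, the inter-profile deltas and
#' their median, the screening partition and the `well_spaced` conjunction
#' (`beta > beta_hi` and `median_delta >= delta_min`).
#'
#' @param members Tibble with `seq_id` and member columns `a_1d` .. `c_3d`.
#' @param cfg A [screen_config()].
#' @param variance,formula,eps Passed to [group_stats()] / [alpha_stat()].
#' @return A `gh9_beta_table` tibble.
#' @export
beta_table <- function(members, cfg = screen_config(),
                       variance = c("population", "sample"),
                       formula = c("tau_sq", "eq2"), eps = 1e-9) {
  variance <- match.arg(variance)
  formula <- match.arg(formula)
  need <- c("seq_id", "a_1d", "a_3d", "b_1d", "b_3d", "c_1d", "c_3d")
  stopifnot(all(need %in% names(members)))
  if ("unclassifiable" %in% names(members) && any(members$unclassifiable)) {
    warn(sprintf("dropping %d unclassifiable sequence(s) from the beta table",
                 sum(members$unclassifiable)))
    members <- dplyr::filter(members, !.data$unclassifiable)
  }
  rows <- purrr::map(seq_len(nrow(members)), function(i) {
    ga <- group_stats(c(members$a_1d[i], members$a_3d[i]), variance)
    gb <- group_stats(c(members$b_1d[i], members$b_3d[i]), variance)
    gc_ <- group_stats(c(members$c_1d[i], members$c_3d[i]), variance)
    ab <- alpha_stat(ga, gb, formula, eps)
    bc <- alpha_stat(gb, gc_, formula, eps)
    ac <- alpha_stat(ga, gc_, formula, eps)
    tibble(seq_id = members$seq_id[i],
           hmm_a = ga$mu, hmm_b = gb$mu, hmm_c = gc_$mu,
           a12 = ab$alpha, a23 = bc$alpha, a13 = ac$alpha,
           z12 = ab$z, z23 = bc$z, z13 = ac$z,
           saturated = ab$saturated || bc$saturated || ac$saturated)
  }) |> dplyr::bind_rows()
  out <- rows |>
    mutate(beta = beta_stat(.data$a12, .data$a23, .data$a13)) |>
    bind_cols(delta_hmm(rows$hmm_a, rows$hmm_b, rows$hmm_c)) |>
    mutate(partition = screen_partition(.data$beta, cfg),
           well_spaced = .data$beta > cfg$beta_hi &
             .data$median_delta >= cfg$delta_min,
           max_class = max_class(.data$hmm_a, .data$hmm_b, .data$hmm_c))
  class(out) <- c("gh9_beta_table", class(out))
  out
}
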