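# Seeded generators of class-architectured protein families, score tables and
# alpha/beta training fixtures. These are first-class, tested components: every
# downstream stage can be exercised end to end without any external data.

#' Specification of a synthetic GH9-like protein family
#'
#' Describes the three architectures the classifier targets: class A carries an
#' N-terminal transmembrane-like hydrophobic segment, class B an N-terminal
#' signal-peptide-like segment, and class C the class-B architecture plus an
#' aromatic-rich (W/F/Y-enriched) 100-120 residue C-terminal module emulating
#' CBM49. All classes share a common catalytic-core ancestor; class cores
#' diverge from it at `class_divergence` substitutions per site (the class C
#' core derives from the class B core at half that rate, since a class C
#' protein is essentially a class B sequence with an appended binding module),
#' and individual family members diverge from their class template at
#' `substitution_rate`.
#'
#' @param n_per_class Integer (length 1 or 3, ordered A, B, C): sequences per
#'   class.
#' @param core_length Length of the shared catalytic core (residues).
#' @param tm_length Length of the class A transmembrane-like segment.
#' @param signal_length Length of the class B/C signal-peptide-like segment.
#' @param cbm_range Length range of the class C aromatic-rich module.
#' @param class_divergence Per-site substitution rate between the ancestor core
#'   and each class core.
#' @param substitution_rate Per-site substitution rate between a class template
#'   and each family member.
#' @param organisms Character vector of organism keys cycled over the members
#'   of each class.
#' @param seed Integer seed; generation is byte-deterministic given the spec.
#' @return A `gh9_family_spec` list.
#' @export
family_spec <- function(n_per_class = c(6L, 16L, 4L),
                        core_length = 450L,
                        tm_length = 23L,
                        signal_length = 20L,
                        cbm_range = c(100L, 120L),
                        class_divergence = 0.15,
                        substitution_rate = 0.05,
                        organisms = c("orgA", "orgB", "orgC"),
                        seed = 1L) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 3L)
  stopifnot(length(n_per_class) == 3L, all(n_per_class >= 0L))
  if (cbm_range[1] < 100L || cbm_range[2] > 120L || cbm_range[1] > cbm_range[2]) {
    abort("cbm_range must lie within [100, 120]")
  }
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      class_divergence < 0 || class_divergence >= 1) {
    abort("substitution rates must lie in [0, 1)")
  }
  structure(
    list(n_per_class = as.integer(n_per_class), core_length = as.integer(core_length),
         tm_length = as.integer(tm_length), signal_length = as.integer(signal_length),
         cbm_range = as.integer(cbm_range), class_divergence = class_divergence,
         substitution_rate = substitution_rate, organisms = organisms,
         seed = as.integer(seed)),
    class = "gh9_family_spec"
  )
}

random_peptide <- function(n, alphabet = AA_ALPHABET, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

mutate_peptide <- function(x, rate) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

# hydrophobic alphabet for TM-like segments; signal-like = M + charged pair +
# hydrophobic stretch + small-residue cleavage region
tm_segment <- function(n) {
  random_peptide(n, alphabet = c("A", "I", "L", "M", "F", "V", "W"))
}

signal_segment <- function(n) {
  stopifnot(n >= 8L)
  body <- random_peptide(n - 6L, alphabet = c("A", "I", "L", "M", "F", "V"))
  paste0("M", random_peptide(2L, alphabet = c("K", "R")), body, "ASA")
}

cbm_segment <- function(n) {
  # roughly 45% aromatic content, the class C discriminator
  prob <- ifelse(AA_ALPHABET %in% c("W", "F", "Y"), 0.15, 0.55 / 17)
  random_peptide(n, prob = prob)
}

#' Generate a labelled synthetic protein family
#'
#' Produces class-architectured toy sequences with known ground truth. The
#' output tibble doubles as the truth table: `class_label` is the planted
#' class of every sequence.
#'
#' @param spec A [family_spec()].
#' @return Tibble with `uid`, `class_label`, `organism`, `residues`.
#' @export
#' @examples
#' fam <- gen_families(family_spec(n_per_class = 2, seed = 7))
#' table(fam$class_label)
gen_families <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "gh9_family_spec"))
  with_seed(spec$seed, {
    ancestor <- random_peptide(spec$core_length)
    core_a <- mutate_peptide(ancestor, spec$class_divergence)
    core_b <- mutate_peptide(ancestor, spec$class_divergence)
    core_c <- mutate_peptide(core_b, spec$class_divergence / 2)
    templates <- list(
      A = paste0("M", tm_segment(spec$tm_length), core_a),
      B = paste0(signal_segment(spec$signal_length), core_b),
      C = paste0(signal_segment(spec$signal_length), core_c,
                 random_peptide(5L, alphabet = c("G", "S")),
                 cbm_segment(sample(seq(spec$cbm_range[1], spec$cbm_range[2]), 1L)))
    )
    out <- purrr::map2(CLASS_LABELS, spec$n_per_class, function(cl, n) {
      if (n == 0L) return(NULL)
      tibble(
        uid = sprintf("SYN%s%03d", cl, seq_len(n)),
        class_label = cl,
        organism = rep_len(spec$organisms, n),
        residues = vapply(seq_len(n), function(i) {
          mutate_peptide(templates[[cl]], spec$substitution_rate)
        }, character(1))
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Specification of a synthetic score table
#'
#' Controls the class-mean separations and within-pair spread of simulated
#' profile bit scores, so the beta statistic and screening filter can be
#' tested against closed-form expectations.
#'
#' @param means 3x3 numeric matrix: row = true class (A, B, C), column =
#'   profile class (A, B, C); entry = expected bit score of that class pair.
#' @param sd Within-pair standard deviation (bits), recycled to length 3 per
#'   profile class.
#' @param n_per_class Sequences per true class (length 1 or 3).
#' @param seed Integer seed.
#' @return A `gh9_score_spec` list.
#' @export
score_table_spec <- function(means = rbind(A = c(500, 250, 150),
                                           B = c(200, 480, 300),
                                           C = c(150, 350, 520)),
                             sd = 5,
                             n_per_class = 10L,
                             seed = 1L) {
  means <- as.matrix(means)
  stopifnot(all(dim(means) == c(3L, 3L)), all(sd >= 0))
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 3L)
  dimnames(means) <- list(CLASS_LABELS, CLASS_LABELS)
  structure(
    list(means = means, sd = rep_len(sd, 3L),
         n_per_class = as.integer(n_per_class), seed = as.integer(seed)),
    class = "gh9_score_spec"
  )
}

#' Generate a synthetic class-pair score table
#'
#' Draws, for each simulated sequence, the six class-pair member scores (the
#' 1D- and 3D-side score of each class group) from Normal(mean, sd). The
#' planted maximum-mean class is recorded as ground truth.
#'
#' @param spec A [score_table_spec()].
#' @return Tibble with `seq_id`, `true_class`, and member columns
#'   `a_1d`, `a_3d`, `b_1d`, `b_3d`, `c_1d`, `c_3d` (bits).
#' @export
gen_score_table <- function(spec = score_table_spec()) {
  stopifnot(inherits(spec, "gh9_score_spec"))
  with_seed(spec$seed, {
    rows <- purrr::map2(CLASS_LABELS, spec$n_per_class, function(cl, n) {
      if (n == 0L) return(NULL)
      mu <- spec$means[cl, ]
      tibble(
        seq_id = sprintf("SIM%s%03d", cl, seq_len(n)),
        true_class = cl,
        a_1d = rnorm(n, mu["A"], spec$sd[1]), a_3d = rnorm(n, mu["A"], spec$sd[1]),
        b_1d = rnorm(n, mu["B"], spec$sd[2]), b_3d = rnorm(n, mu["B"], spec$sd[2]),
        c_1d = rnorm(n, mu["C"], spec$sd[3]), c_3d = rnorm(n, mu["C"], spec$sd[3])
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate alpha-triple / target training fixtures
#'
#' Draws alpha triples from class-conditional lognormal-ish distributions and
#' sets the regression target to the weighted combination
#' `sum(gamma * alpha) + Normal(0, noise_sd)`, the linear model the network is
#' expected to recover.
#'
#' @param n Number of rows (>= 3), spread round-robin over the three classes.
#' @param gamma Length-3 weights for (a12, a23, a13).
#' @param noise_sd Standard deviation of the additive target noise.
#' @param seed Integer seed.
#' @param class_alpha_means 3x3 matrix of class-conditional alpha means
#'   (rows A, B, C; columns a12, a23, a13).
#' @param alpha_spread Within-class coefficient of variation of the alpha
#'   draws (0.15 by default; small values emulate perfectly separated
#'   classes).
#' @return Tibble with `seq_id`, `class_label`, `a12`, `a23`, `a13`, `target`.
#' @export
gen_alpha_beta <- function(n, gamma = c(1, 1, 1), noise_sd = 0, seed = 1L,
                           class_alpha_means = rbind(A = c(3.0, 1.2, 4.0),
                                                     B = c(1.6, 1.2, 1.1),
                                                     C = c(1.2, 3.2, 2.5)),
                           alpha_spread = 0.15) {
  stopifnot(n >= 3L, length(gamma) == 3L, noise_sd >= 0, alpha_spread >= 0)
  class_alpha_means <- as.matrix(class_alpha_means)
  with_seed(seed, {
    cl <- rep_len(CLASS_LABELS, n)
    a <- t(vapply(cl, function(k) {
      abs(rnorm(3L, class_alpha_means[k, ], alpha_spread * class_alpha_means[k, ]))
    }, numeric(3)))
    dimnames(a) <- NULL
    tibble(
      seq_id = sprintf("FIX%03d", seq_len(n)),
      class_label = cl,
      a12 = a[, 1], a23 = a[, 2], a13 = a[, 3],
      target = as.numeric(a %*% gamma) + rnorm(n, 0, noise_sd)
    )
  })
}
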