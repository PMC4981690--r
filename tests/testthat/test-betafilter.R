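# The alpha/beta disambiguation statistic, the deltas and the screen.

test_that("group statistics use the population variance over two members", {
  g <- group_stats(c(100, 110))
  expect_equal(g$mu, 105)
  expect_equal(g$sigma2, 25)  # ((100-105)^2 + (110-105)^2)/2
  expect_equal(g$tau, 2L)
  expect_equal(group_stats(c(300, 300))$sigma2, 0)
  expect_equal(group_stats(c(0, 0))$mu, 0)
  expect_equal(group_stats(c(100, 110), variance = "sample")$sigma2, 50)
  expect_error(group_stats(c(1, 2, 3)), "two finite members")
  expect_error(group_stats(c(1, Inf)), "two finite members")
})

test_that("alpha evaluates the adopted formula and its guards", {
  g <- function(mu, s2) structure(list(mu = mu, sigma2 = s2, tau = 2L),
                                  class = "gh9_group")
  # hand computation: 2^2 * (210-105)^2 / (100 * (25+75)) = 44100/10000
  expect_equal(alpha_stat(g(105, 25), g(210, 75))$alpha, 4.41)
  # equal means give zero regardless of variances
  expect_equal(alpha_stat(g(50, 3), g(50, 900))$alpha, 0)
  # zero-variance guard saturates instead of overflowing
  sat <- alpha_stat(g(1, 0), g(2, 0))
  expect_true(sat$saturated)
  expect_true(is.finite(sat$alpha))
  # the z diagnostic is the inter-group z-score
  a <- alpha_stat(g(105, 25), g(210, 75))
  expect_equal(a$z, 105 / sqrt((25 + 75) / 2))
  # alternative parenthesization is exposed and differs in general
  expect_false(isTRUE(all.equal(
    alpha_stat(g(105, 25), g(210, 75), formula = "eq2")$alpha, 4.41)))
})

test_that("alpha is symmetric and scale invariant", {
  set.seed(11)
  for (i in 1:50) {
    m1 <- runif(2, 0, 500); m2 <- runif(2, 0, 500)
    g1 <- group_stats(m1); g2 <- group_stats(m2)
    expect_equal(alpha_stat(g1, g2)$alpha, alpha_stat(g2, g1)$alpha)
    cc <- runif(1, 0.1, 10)
    expect_equal(alpha_stat(group_stats(cc * m1), group_stats(cc * m2))$alpha,
                 alpha_stat(g1, g2)$alpha)
    # adding a constant to all members leaves alpha unchanged
    k <- runif(1, -100, 100)
    expect_equal(alpha_stat(group_stats(m1 + k), group_stats(m2 + k))$alpha,
                 alpha_stat(g1, g2)$alpha)
  }
})

test_that("alpha is inversely proportional to the pooled variance", {
  g <- function(mu, s2) structure(list(mu = mu, sigma2 = s2, tau = 2L),
                                  class = "gh9_group")
  base <- alpha_stat(g(100, 20), g(300, 40))$alpha
  doubled <- alpha_stat(g(100, 40), g(300, 80))$alpha
  expect_equal(doubled, base / 2)
})

test_that("beta is monotone in each mean separation at fixed variances", {
  g <- function(mu, s2) structure(list(mu = mu, sigma2 = s2, tau = 2L),
                                  class = "gh9_group")
  # move group 2 away from both ends simultaneously is not monotone; the
  # property holds per pairwise separation: each alpha is non-decreasing in
  # its own |mu_i - mu_j| at fixed variances, hence so is their sum
  for (s2 in c(10, 30, 200)) {
    a <- vapply(seq(0, 400, by = 25), function(d) {
      alpha_stat(g(100, s2), g(100 + d, s2))$alpha
    }, numeric(1))
    expect_true(all(diff(a) >= 0))
  }
  # and beta inherits it when one gap widens with the others fixed
  betas <- vapply(seq(0, 200, by = 20), function(d) {
    beta_stat(alpha_stat(g(100, 30), g(300 + d, 30))$alpha,
              alpha_stat(g(300 + d, 30), g(900, 30))$alpha * 0 + 1,
              alpha_stat(g(100, 30), g(900, 30))$alpha)
  }, numeric(1))
  expect_true(all(diff(betas) >= 0))
})

test_that("beta equals the brute-force halved double sum on 1000 random triples", {
  set.seed(99)
  a <- matrix(runif(3000, 0, 50), ncol = 3)
  expect_equal(beta_stat(a[, 1], a[, 2], a[, 3]),
               vapply(seq_len(nrow(a)), function(i) brute_beta(a[i, 1], a[i, 2], a[i, 3]),
                      numeric(1)))
  expect_equal(beta_stat(0, 0, 0), 0)
  expect_equal(beta_stat(44.1, 1.0, 2.5), 47.6)
})

test_that("inter-profile deltas and their median use the middle order statistic", {
  d <- delta_hmm(500, 300, 100)
  expect_equal(c(d$d_ab, d$d_bc, d$d_ac), c(200, 200, 400))
  expect_equal(d$median_delta, 200)
  expect_equal(delta_hmm(300, 300, 300)$median_delta, 0)
  # vectorised
  dv <- delta_hmm(c(500, 300), c(300, 300), c(100, 300))
  expect_equal(dv$median_delta, c(200, 0))
})

test_that("the screen partitions beta and reports spacing separately", {
  cfg <- screen_config()
  expect_equal(screen_partition(c(10, 2.777, 1.5, 1.0, 0.5), cfg),
               c("AA", "AB", "AB", "AB", "AC"))
  # boundary case: beta exactly at the upper threshold is intermediate
  expect_identical(screen_partition(2.777, cfg), "AB")
  st <- gen_score_table(score_table_spec(n_per_class = 4, seed = 2))
  bt <- beta_table(st)
  expect_equal(bt$well_spaced, bt$partition == "AA" & bt$median_delta >= 200)
  expect_error(screen_config(beta_hi = 1, beta_lo = 2), "below")
})

test_that("the beta table reproduces closed-form values on noiseless score tables", {
  sp <- score_table_spec(means = rbind(A = c(500, 200, 100),
                                       B = c(500, 200, 100),
                                       C = c(500, 200, 100)),
                         sd = 0, n_per_class = 2, seed = 1)
  bt <- beta_table(gen_score_table(sp))
  # zero within-pair spread: every alpha saturates at the eps floor 1e-9
  expect_true(all(bt$saturated))
  expect_equal(bt$a12[1], 4 * 300^2 / (100 * 1e-9))
  expect_equal(bt$a23[1], 4 * 100^2 / (100 * 1e-9))
  expect_equal(bt$a13[1], 4 * 400^2 / (100 * 1e-9))
  expect_equal(bt$beta, bt$a12 + bt$a23 + bt$a13)
  expect_equal(bt$median_delta[1], 300)
})

test_that("the beta table is invariant to profile column order", {
  st <- gen_score_table(score_table_spec(n_per_class = 3, seed = 8))
  shuffled <- st[, c("seq_id", "c_3d", "a_1d", "b_3d", "true_class", "a_3d", "c_1d", "b_1d")]
  expect_equal(beta_table(st)$beta, beta_table(shuffled)$beta)
})
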