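# The assignment rule table, evaluation framework and taxonomy summaries.

test_that("the default rule table reproduces the worked assignments", {
  cases <- tibble::tibble(
    seq_id = sprintf("q%d", 1:7),
    beta_pp = c(9.0, 10.2, 10.2, 4.0, 7.0, 2.0, 10.2),
    alpha13 = c(0, 0.01, 0.05, 0, 0, 0, 0.02)
  )
  got <- assign_class(cases)
  expect_equal(got$label,
               c("C", "A", "C", "B_high", "B_low", "unassigned", "unassigned"))
  expect_equal(got$confidence[4:5], c("B+", "B-"))
  expect_true(is.na(got$confidence[6]))
  # closed/open boundary memberships exactly as printed
  bounds <- assign_class(tibble::tibble(
    seq_id = sprintf("b%d", 1:6),
    beta_pp = c(8.2052, 9.95, 10.779, 11.371, 3.45, 5.55),
    alpha13 = 0
  ))
  expect_equal(bounds$label, c("C", "C", "C", "C", "unassigned", "B_low"))
  # outside every interval
  expect_equal(assign_class(tibble::tibble(seq_id = "x", beta_pp = 12, alpha13 = 0))$label,
               "unassigned")
})

test_that("rule tables are validated for disjointness on a dense grid", {
  rules <- default_rules()
  grid <- expand.grid(beta_pp = seq(0, 12, by = 0.004),
                      alpha13 = c(0, 0.01, 0.02, 0.03))
  m <- gh9class:::match_rules(grid$beta_pp, grid$alpha13, rules)
  expect_true(all(m$n_labels <= 1L))
  # an overlapping table is rejected at load time
  bad <- rules
  bad$hi[bad$label == "B_high"] <- 6.0  # now overlaps B_low on [5.55, 6)
  expect_error(validate_rules(bad), "overlapping")
  # empty intervals are rejected
  bad2 <- rules
  bad2$lo[1] <- bad2$hi[1]
  expect_error(validate_rules(bad2), "empty interval")
})

test_that("rule tables round-trip through YAML", {
  p <- tempfile(fileext = ".yaml")
  write_rules_yaml(default_rules(), p)
  back <- read_rules_yaml(p)
  expect_equal(as.data.frame(back), as.data.frame(default_rules()))
})

test_that("derived rules recover planted class intervals", {
  set.seed(8)
  beta_pp <- c(runif(20, 3.5, 4.5), runif(20, 6.5, 7.5), runif(20, 9, 10))
  ref <- rep(c("B", "C", "A"), each = 20)
  rules <- derive_rules(beta_pp, ref)
  expect_setequal(rules$label, c("A", "B_high", "C"))
  a <- rules[rules$label == "A", ]
  expect_equal(c(a$lo, a$hi), range(beta_pp[ref == "A"]))
  # assignments from derived rules reproduce the planted classes
  got <- assign_class(tibble::tibble(seq_id = seq_along(beta_pp),
                                     beta_pp = beta_pp, alpha13 = 0), rules)
  expect_equal(ifelse(got$label == "B_high", "B", got$label), ref)
  # overlapping classes cannot yield a valid table
  expect_error(derive_rules(c(1, 2, 3, 2.5, 3.5, 4), rep(c("A", "B"), each = 3)),
               "overlapping")
})

test_that("evaluation counts match an independent tally and the printed identities", {
  set.seed(14)
  n <- 120
  truth <- sample(c("A", "B", "C"), n, replace = TRUE)
  label <- ifelse(runif(n) < 0.7, ifelse(truth == "B", "B_high", truth),
                  sample(c("A", "B_low", "C", "unassigned"), n, replace = TRUE))
  part <- sample(c("AA", "AB", "AC"), n, replace = TRUE)
  ev <- evaluate_assignments(
    tibble::tibble(seq_id = 1:n, label = label),
    tibble::tibble(seq_id = 1:n, reference = truth),
    tibble::tibble(seq_id = 1:n, partition = part)
  )
  expect_equal(ev$M + ev$MM + ev$NM, ev$n_seq)
  expect_equal(sum(ev$recall), 1)
  for (p in ev$partition) {
    o <- brute_confusion(label[part == p], truth[part == p])
    row <- ev[ev$partition == p, ]
    expect_equal(c(row$M, row$MM, row$NM), unname(o))
    expect_equal(row$precision, o["M"] / sum(o), ignore_attr = TRUE)
  }
  # all-matched single partition: precision = recall = 1
  ev1 <- evaluate_assignments(
    tibble::tibble(seq_id = 1:4, label = c("A", "B_high", "B_low", "C")),
    tibble::tibble(seq_id = 1:4, reference = c("A", "B", "B", "C")),
    tibble::tibble(seq_id = 1:4, partition = "AA")
  )
  expect_equal(ev1$precision, 1)
  expect_equal(ev1$recall, 1)
})

test_that("pooled delta summaries cover the three deltas of each matched sequence", {
  ev <- evaluate_assignments(
    tibble::tibble(seq_id = 1:3, label = c("A", "A", "unassigned")),
    tibble::tibble(seq_id = 1:3, reference = c("A", "B", "C")),
    tibble::tibble(seq_id = 1:3, partition = "AA",
                   d_ab = c(10, 20, 30), d_bc = c(40, 50, 60), d_ac = c(70, 80, 90))
  )
  # only the single matched sequence contributes: deltas 10/40/70
  expect_equal(ev$n_deltas, 3L)
  expect_equal(ev$delta_median, 40)
  expect_equal(ev$delta_mean, 40)
})

test_that("taxonomy summaries count planted labels per organism", {
  asg <- tibble::tibble(
    organism = rep(c("osat", "atha", "zmay"), each = 4),
    label = rep(c("A", "B_high", "B_low", "C"), 3),
    partition = c(rep("AA", 8), "AA", "AA", "AB", "AC")
  )
  tx <- summarize_taxonomy(asg)
  expect_equal(nrow(tx), 3L)
  expect_equal(unlist(tx[tx$organism == "osat", c("A", "B_high", "B_low", "C", "total")]),
               c(A = 1L, B_high = 1L, B_low = 1L, C = 1L, total = 4L))
  expect_equal(tx$total[tx$organism == "zmay"], 2L)
  # identical assignment sets give identical rows
  expect_equal(unlist(tx[tx$organism == "osat", -1]),
               unlist(tx[tx$organism == "atha", -1]))
  # empty input gives an empty table
  empty <- summarize_taxonomy(tibble::tibble(organism = character(), label = character()))
  expect_equal(nrow(empty), 0L)
})
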