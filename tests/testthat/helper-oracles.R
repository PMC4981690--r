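# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and literal formula
# transcriptions, kept as dumb as possible.

# beta as the literal halved 3x3 double sum over distinct indices
brute_beta <- function(a12, a23, a13) {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- a12
  a[2, 3] <- a[3, 2] <- a23
  a[1, 3] <- a[3, 1] <- a13
  total <- 0
  for (i in 1:3) for (j in 1:3) if (i != j) total <- total + a[i, j]
  total / 2
}

# exhaustive k=3 partition minimiser of within-cluster SS for 1-D points;
# enumerates all 3^n label assignments with three non-empty groups
brute_kmeans3 <- function(x) {
  n <- length(x)
  stopifnot(n <= 8L)
  best <- list(ss = Inf)
  grid <- expand.grid(rep(list(1:3), n))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < 3L) next
    ss <- sum(vapply(1:3, function(k) {
      v <- x[lab == k]
      sum((v - mean(v))^2)
    }, numeric(1)))
    if (ss < best$ss) {
      best <- list(ss = ss, labels = lab,
                   centers = vapply(1:3, function(k) mean(x[lab == k]), numeric(1)))
    }
  }
  best
}

# leave-one-out retention rule, re-derived by direct filtering of the
# registry tibble (no calls into select_loocv)
brute_loocv_retained <- function(registry, target_uid) {
  loo <- registry[registry$scope == "loocv", ]
  target_class <- unique(loo$class_label[!is.na(loo$excluded_uid) &
                                           loo$excluded_uid == target_uid])
  keep <- loo$class_label != target_class |
    (!is.na(loo$excluded_uid) & loo$excluded_uid == target_uid)
  sort(loo$profile_id[keep])
}

# independent confusion tally for evaluation tests
brute_confusion <- function(label, reference) {
  collapsed <- ifelse(label %in% c("B_high", "B_low"), "B", label)
  c(M = sum(collapsed == reference & collapsed != "unassigned"),
    MM = sum(collapsed != reference & collapsed != "unassigned"),
    NM = sum(collapsed == "unassigned"))
}

random_training_meta <- function(n_per_class) {
  tibble::tibble(
    uid = sprintf("T%s%02d", rep(c("A", "B", "C"), n_per_class),
                  unlist(lapply(n_per_class, seq_len))),
    class_label = rep(c("A", "B", "C"), n_per_class)
  )
}
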