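# One-dimensional k-means on training beta values: seeded k-means++ restarts,
# best model by between_SS/total_SS, cluster -> class mapping by majority
# training label, and outlier exclusion with refit.

#' Clustering configuration
#'
#' @param k Number of clusters (3 for the A/B/C schema).
#' @param n_init Number of seeded k-means++ restarts.
#' @param seed Integer seed for initialisation.
#' @param outlier_method `"manual"` (a configured uid list, the default) or
#'   `"centroid_distance"` (points more than `outlier_sd` within-cluster
#'   standard deviations from their centroid).
#' @param outlier_sd Threshold in within-cluster SD units.
#' @param manual_exclude Character vector of uids for manual exclusion.
#' @return A `gh9_cluster_config` list.
#' @export
cluster_config <- function(k = 3L, n_init = 100L, seed = 1L,
                           outlier_method = c("manual", "centroid_distance"),
                           outlier_sd = 2.5, manual_exclude = character()) {
  outlier_method <- match.arg(outlier_method)
  stopifnot(k >= 1L, n_init >= 1L, outlier_sd > 0)
  structure(list(k = as.integer(k), n_init = as.integer(n_init),
                 seed = as.integer(seed), outlier_method = outlier_method,
                 outlier_sd = outlier_sd, manual_exclude = manual_exclude),
            class = "gh9_cluster_config")
}

# k-means++ seeding in 1-D: first centre uniform, then distance^2-weighted
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1L)]
  if (k > 1L) {
    for (j in 2:k) {
      d2 <- vapply(x, function(v) min((v - centers[1:(j - 1)])^2), numeric(1))
      if (all(d2 == 0)) {
        centers[j] <- x[sample.int(length(x), 1L)]
      } else {
        centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
      }
    }
  }
  centers
}

#' Cluster training beta values and map clusters to classes
#'
#' Runs `cfg$n_init` seeded k-means++ restarts of [stats::kmeans()] on the
#' one-dimensional beta values and keeps the fit with the highest
#' between-SS/total-SS ratio. Clusters are mapped to classes by the majority
#' training label of their members; an ambiguous majority or two clusters
#' claiming the same class is a mapping error.
#'
#' @param values Tibble with `seq_id`, `beta`, `class_label` columns (training
#'   labels), e.g. a [beta_table()] joined to its metadata.
#' @param cfg A [cluster_config()].
#' @return A `gh9_cluster` object: `centroids` (named A/B/C), `assignments`
#'   tibble, `ss_ratio`, `excluded_uids`, `config`.
#' @export
cluster_betas <- function(values, cfg = cluster_config()) {
  stopifnot(all(c("seq_id", "beta", "class_label") %in% names(values)))
  stopifnot(inherits(cfg, "gh9_cluster_config"))
  assert_class_label(values$class_label)
  x <- values$beta
  if (length(unique(x)) < cfg$k) {
    abort(sprintf("k-means with k=%d needs at least %d distinct beta values (got %d)",
                  cfg$k, cfg$k, length(unique(x))))
  }
  fits <- with_seed(cfg$seed, {
    purrr::map(seq_len(cfg$n_init), function(i) {
      centers <- unique(kmeanspp_centers(x, cfg$k))
      if (length(centers) < cfg$k) return(NULL)
      fit <- suppressWarnings(
        tryCatch(stats::kmeans(x, centers = matrix(centers, ncol = 1)),
                 error = function(e) NULL))
      fit
    })
  })
  fits <- purrr::keep(fits, ~ !is.null(.x) && all(.x$size > 0))
  if (length(fits) == 0L) abort("k-means failed on every restart (degenerate input)")
  ratios <- purrr::map_dbl(fits, ~ .x$betweenss / .x$totss)
  best <- fits[[which.max(ratios)]]
  # majority-label mapping, cluster -> class
  assignments <- tibble(seq_id = values$seq_id, beta = x,
                        class_label = values$class_label,
                        cluster = best$cluster)
  mapping <- assignments |>
    count(.data$cluster, .data$class_label) |>
    group_by(.data$cluster) |>
    dplyr::slice_max(.data$n, n = 1L, with_ties = TRUE) |>
    ungroup()
  if (anyDuplicated(mapping$cluster)) {
    abort("cluster -> class mapping error: a cluster has a tied majority label")
  }
  if (anyDuplicated(mapping$class_label)) {
    abort("cluster -> class mapping error: two clusters share a majority label")
  }
  cluster_class <- setNames(mapping$class_label, mapping$cluster)
  centroids <- setNames(as.numeric(best$centers),
                        cluster_class[as.character(seq_len(cfg$k))])
  centroids <- centroids[CLASS_LABELS[CLASS_LABELS %in% names(centroids)]]
  assignments$mapped_class <- unname(cluster_class[as.character(assignments$cluster)])
  structure(
    list(centroids = centroids, assignments = assignments,
         ss_ratio = max(ratios), excluded_uids = character(), config = cfg),
    class = "gh9_cluster"
  )
}

#' Identify outliers in a fitted cluster model
#'
#' Manual mode returns the configured uid list (intersected with the data);
#' centroid-distance mode flags points more than `cfg$outlier_sd`
#' within-cluster standard deviations from their centroid.
#'
#' @param model A fitted [cluster_betas()] model.
#' @param cfg A [cluster_config()].
#' @return Character vector of excluded uids (possibly empty).
#' @export
exclude_outliers <- function(model, cfg = model$config) {
  stopifnot(inherits(model, "gh9_cluster"))
  if (cfg$outlier_method == "manual") {
    return(intersect(cfg$manual_exclude, model$assignments$seq_id))
  }
  a <- model$assignments
  flagged <- a |>
    group_by(.data$cluster) |>
    mutate(center = mean(.data$beta),
           spread = stats::sd(.data$beta)) |>
    ungroup() |>
    filter(!is.na(.data$spread), .data$spread > 0,
           abs(.data$beta - .data$center) / .data$spread > cfg$outlier_sd)
  flagged$seq_id
}

#' Fit class centroids with outlier exclusion and refit
#'
#' Fits a preliminary k-means model, removes the outliers identified by
#' [exclude_outliers()], and refits on the retained sequences. The refitted
#' model records the excluded uids.
#'
#' @inheritParams cluster_betas
#' @return A `gh9_cluster` object fitted to the retained sequences.
#' @export
fit_centroids <- function(values, cfg = cluster_config()) {
  prelim <- cluster_betas(values, cfg)
  out <- exclude_outliers(prelim, cfg)
  if (length(out) == 0L) return(prelim)
  refit <- cluster_betas(dplyr::filter(values, !.data$seq_id %in% out), cfg)
  refit$excluded_uids <- out
  refit
}

#' @export
print.gh9_cluster <- function(x, ...) {
  cat(sprintf("<gh9 cluster model> k=%d, n=%d, between_SS/total_SS = %.4f\n",
              x$config$k, nrow(x$assignments), x$ss_ratio))
  cat("centroids (beta'):",
      paste(sprintf("%s=%.4f", names(x$centroids), x$centroids), collapse = "  "), "\n")
  if (length(x$excluded_uids)) {
    cat("excluded outliers:", paste(x$excluded_uids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialise a cluster model to JSON
#'
#' @param model A `gh9_cluster`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cluster_json <- function(model, path) {
  stopifnot(inherits(model, "gh9_cluster"))
  jsonlite::write_json(
    list(centroids = as.list(model$centroids),
         assignments = model$assignments,
         ss_ratio = model$ss_ratio,
         excluded = model$excluded_uids),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
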