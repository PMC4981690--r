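# broom-style tidiers for the fitted objects.

#' Tidy a cluster model
#'
#' @param x A [fit_centroids()] / [cluster_betas()] model.
#' @param ... Unused.
#' @return One row per class: `class_label`, `centroid`, `n`.
#' @method tidy gh9_cluster
#' @export
tidy.gh9_cluster <- function(x, ...) {
  counts <- dplyr::count(x$assignments, .data$mapped_class, name = "n")
  tibble(class_label = names(x$centroids),
         centroid = unname(x$centroids)) |>
    left_join(counts, by = c(class_label = "mapped_class"))
}

#' @rdname tidy.gh9_cluster
#' @method glance gh9_cluster
#' @export
glance.gh9_cluster <- function(x, ...) {
  tibble(k = x$config$k, n = nrow(x$assignments), ss_ratio = x$ss_ratio,
         n_excluded = length(x$excluded_uids))
}

#' Tidy a trained network
#'
#' @param x A [ann_train()] model.
#' @param ... Unused.
#' @return One row per weight: `layer`, `unit`, `input`, `weight` (biases have
#'   `input = "bias"`).
#' @method tidy gh9_ann
#' @export
tidy.gh9_ann <- function(x, ...) {
  purrr::imap(x$weights$W, function(W, l) {
    dplyr::bind_rows(
      tibble(layer = l,
             unit = rep(seq_len(nrow(W)), ncol(W)),
             input = as.character(rep(seq_len(ncol(W)), each = nrow(W))),
             weight = as.numeric(W)),
      tibble(layer = l, unit = seq_along(x$weights$b[[l]]),
             input = "bias", weight = x$weights$b[[l]])
    )
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.gh9_ann
#' @method glance gh9_ann
#' @export
glance.gh9_ann <- function(x, ...) {
  tibble(n_weights = x$n_weights, converged = x$converged, steps = x$steps,
         training_error = x$training_error)
}

#' Tidy a leave-one-out validation
#'
#' @param x An [ann_loocv()] result.
#' @param ... Unused.
#' @return The per-sequence tibble (`seq_id`, `class_label`, `beta_pp`,
#'   `expected`, `nearest_class`, `matched`).
#' @method tidy gh9_loocv
#' @export
tidy.gh9_loocv <- function(x, ...) {
  x$per_seq
}

#' @rdname tidy.gh9_loocv
#' @method glance gh9_loocv
#' @export
glance.gh9_loocv <- function(x, ...) {
  tibble(n = nrow(x$per_seq), chi2 = x$chi2, df = x$df, p_value = x$p_value,
         rmse = sqrt(mean((x$per_seq$beta_pp - x$per_seq$expected)^2)),
         match_rate = mean(x$per_seq$matched))
}
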