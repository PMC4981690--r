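# ggplot2 displays for the main result types.

#' Plot a beta table
#'
#' Beta per sequence (ranked), coloured by screening partition, with the two
#' screening thresholds drawn as horizontal lines.
#'
#' @param object A [beta_table()].
#' @param cfg The [screen_config()] used (for the threshold lines).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gh9_beta_table
#' @export
autoplot.gh9_beta_table <- function(object, cfg = screen_config(), ...) {
  d <- object |>
    arrange(dplyr::desc(.data$beta)) |>
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$beta,
                                  colour = .data$partition)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(cfg$beta_lo, cfg$beta_hi),
                        linetype = "dashed") +
    ggplot2::labs(x = "sequence (ranked by beta)", y = "beta",
                  colour = "partition") +
    ggplot2::theme_minimal()
}

#' Plot a cluster model
#'
#' One-dimensional strip of training beta values by mapped class with the
#' class centroids marked.
#'
#' @param object A [fit_centroids()] model.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gh9_cluster
#' @export
autoplot.gh9_cluster <- function(object, ...) {
  cent <- tidy(object)
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$mapped_class, y = .data$beta)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::geom_point(data = cent,
                        ggplot2::aes(x = .data$class_label, y = .data$centroid),
                        shape = 4, size = 4, colour = "red") +
    ggplot2::labs(x = "mapped class", y = "beta",
                  subtitle = sprintf("between_SS/total_SS = %.3f", object$ss_ratio)) +
    ggplot2::theme_minimal()
}

#' Plot a leave-one-out validation
#'
#' Predicted beta'' against the expected class centroid beta', by class.
#'
#' @param object An [ann_loocv()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gh9_loocv
#' @export
autoplot.gh9_loocv <- function(object, ...) {
  ggplot2::ggplot(object$per_seq,
                  ggplot2::aes(x = .data$expected, y = .data$beta_pp,
                               colour = .data$class_label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "expected (class centroid beta')",
                  y = "predicted beta''", colour = "class") +
    ggplot2::theme_minimal()
}
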