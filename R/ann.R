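# A small feed-forward network mapping the alpha triple (a12, a23, a13) to an
# approximation beta'' of the class centroid beta'. Logistic hidden units,
# identity output, sum-of-squares error, full-batch resilient backpropagation
# (rprop+ with weight backtracking), stopping when every component of the
# error gradient falls below a threshold.

#' Network training configuration
#'
#' @param hidden Integer vector of hidden-layer sizes; the default `10` is a
#'   single hidden layer of 10 units (pass e.g. `rep(10, 10)` for a literal
#'   ten-layer stack, non-default).
#' @param threshold Stopping threshold on the maximum absolute component of
#'   the error gradient.
#' @param max_steps Iteration cap; hitting it returns a model flagged
#'   `converged = FALSE` with a warning.
#' @param seed Integer seed for weight initialisation.
#' @param scale_inputs Standardise inputs before training (default off,
#'   matching the raw-alpha convention); the scaling is stored and re-applied
#'   at prediction.
#' @return A `gh9_ann_config` list.
#' @export
ann_config <- function(hidden = 10L, threshold = 0.01, max_steps = 1e5,
                       seed = 1L, scale_inputs = FALSE) {
  stopifnot(all(hidden >= 1L), threshold > 0, max_steps >= 1)
  structure(list(hidden = as.integer(hidden), threshold = threshold,
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 scale_inputs = isTRUE(scale_inputs)),
            class = "gh9_ann_config")
}

alpha_matrix <- function(data) {
  if (is.matrix(data)) {
    stopifnot(ncol(data) == 3L)
    return(unname(data))
  }
  stopifnot(all(c("a12", "a23", "a13") %in% names(data)))
  unname(as.matrix(data[, c("a12", "a23", "a13")]))
}

ann_forward <- function(weights, X) {
  L <- length(weights$W)
  A <- X
  acts <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- A %*% t(weights$W[[l]])
    Z <- sweep(Z, 2L, weights$b[[l]], "+")
    A <- if (l < L) plogis(Z) else Z
    acts[[l]] <- A
  }
  list(yhat = as.numeric(A), acts = acts)
}

ann_gradient <- function(weights, X, y) {
  L <- length(weights$W)
  fwd <- ann_forward(weights, X)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix(fwd$yhat - y, ncol = 1L)  # dE/dZ_out for E = 0.5*SSE
  for (l in rev(seq_len(L))) {
    A_prev <- if (l == 1L) X else fwd$acts[[l - 1L]]
    gW[[l]] <- t(delta) %*% A_prev
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      A <- fwd$acts[[l - 1L]]
      delta <- (delta %*% weights$W[[l]]) * A * (1 - A)
    }
  }
  list(gW = gW, gb = gb, error = 0.5 * sum((fwd$yhat - y)^2))
}

#' Train the centroid-approximating network
#'
#' @param data Tibble with alpha columns `a12`, `a23`, `a13` (or a 3-column
#'   matrix).
#' @param target Numeric vector of training targets (each sequence's class
#'   centroid beta').
#' @param cfg An [ann_config()].
#' @return A `gh9_ann` model: weight matrices, convergence flag, step count,
#'   final sum-of-squares training error and the configuration.
#' @export
ann_train <- function(data, target, cfg = ann_config()) {
  stopifnot(inherits(cfg, "gh9_ann_config"))
  X <- alpha_matrix(data)
  y <- as.numeric(target)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L, all(is.finite(X)), all(is.finite(y)))
  scaling <- NULL
  if (cfg$scale_inputs) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
    scaling <- list(center = ctr, scale = scl)
  }
  sizes <- c(ncol(X), cfg$hidden, 1L)
  weights <- with_seed(cfg$seed, {
    list(
      W = purrr::map(seq_len(length(sizes) - 1L), function(l) {
        matrix(rnorm(sizes[l + 1L] * sizes[l]), nrow = sizes[l + 1L])
      }),
      b = purrr::map(seq_len(length(sizes) - 1L), function(l) rnorm(sizes[l + 1L]))
    )
  })
  skeleton <- weights
  w <- unlist(weights, use.names = FALSE)
  # rprop+ state
  step <- rep(0.1, length(w))
  prev_g <- rep(0, length(w))
  prev_dw <- rep(0, length(w))
  eta_plus <- 1.2; eta_minus <- 0.5; step_max <- 50; step_min <- 1e-6
  converged <- FALSE
  steps <- 0L
  err <- NA_real_
  repack <- function(v) utils::relist(v, skeleton)
  for (it in seq_len(cfg$max_steps)) {
    gr <- ann_gradient(repack(w), X, y)
    g <- unlist(list(W = gr$gW, b = gr$gb), use.names = FALSE)
    err <- gr$error
    steps <- it
    if (max(abs(g)) < cfg$threshold) {
      converged <- TRUE
      break
    }
    s <- g * prev_g
    up <- s > 0
    down <- s < 0
    step[up] <- pmin(step[up] * eta_plus, step_max)
    step[down] <- pmax(step[down] * eta_minus, step_min)
    dw <- -sign(g) * step
    dw[down] <- -prev_dw[down]  # backtrack the previous move
    w <- w + dw
    g[down] <- 0                # suppress adaptation on the next iteration
    prev_g <- g
    prev_dw <- dw
  }
  if (!converged) {
    warn(sprintf("network did not converge in %d steps (max |gradient| still above %.g)",
                 cfg$max_steps, cfg$threshold))
  }
  structure(
    list(weights = repack(w), scaling = scaling, converged = converged,
         steps = steps, training_error = err, config = cfg,
         n_weights = length(w)),
    class = "gh9_ann"
  )
}

#' Predict beta'' for alpha triples
#'
#' Deterministic forward pass through a trained network.
#'
#' @param object A `gh9_ann` model.
#' @param newdata Tibble with `a12`, `a23`, `a13` (or a 3-column matrix).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gh9_ann <- function(object, newdata, ...) {
  X <- alpha_matrix(newdata)
  if (!is.null(object$scaling)) {
    X <- sweep(sweep(X, 2L, object$scaling$center), 2L, object$scaling$scale, "/")
  }
  ann_forward(object$weights, X)$yhat
}

#' @export
print.gh9_ann <- function(x, ...) {
  sizes <- c(ncol(x$weights$W[[1]]), vapply(x$weights$W, nrow, integer(1)))
  cat(sprintf("<gh9 ann> topology %s (%d weights), %s after %d steps, SSE/2 = %.4g\n",
              paste(sizes, collapse = "-"), x$n_weights,
              if (x$converged) "converged" else "NOT converged", x$steps,
              x$training_error))
  invisible(x)
}

#' Chi-squared agreement between predicted and expected values
#'
#' `chi2 = sum((obs - exp)^2 / exp)` with `df = n - 1`, the summary used to
#' compare network predictions with their class centroids.
#'
#' @param observed,expected Equal-length numeric vectors; `expected` must be
#'   strictly positive.
#' @return List with `chi2`, `df` and the upper-tail `p_value` (reported for
#'   completeness, not interpreted).
#' @export
chi_squared <- function(observed, expected) {
  if (length(observed) != length(expected)) abort("lengths differ")
  if (any(expected <= 0)) abort("expected values must be > 0")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Leave-one-out validation of the network against the class centroids
#'
#' For every sequence, trains the network on the remaining sequences (targets
#' are the class centroids beta') and predicts the held-out alpha triple; the
#' expectation is the held-out sequence's own class centroid. Sequences whose
#' removal would empty their class are skipped with a warning.
#'
#' @param data Tibble with `seq_id`, `class_label`, `a12`, `a23`, `a13`.
#' @param centroids Named numeric vector of class centroids (A/B/C), or a
#'   [fit_centroids()] model.
#' @param cfg An [ann_config()].
#' @return A `gh9_loocv` object: per-sequence tibble (`seq_id`, `class_label`,
#'   `beta_pp`, `expected`, `matched`), `chi2`, `df`, `p_value`.
#' @export
ann_loocv <- function(data, centroids, cfg = ann_config()) {
  if (inherits(centroids, "gh9_cluster")) centroids <- centroids$centroids
  stopifnot(all(CLASS_LABELS %in% names(centroids)))
  stopifnot(all(c("seq_id", "class_label", "a12", "a23", "a13") %in% names(data)))
  assert_class_label(data$class_label)
  y <- unname(centroids[data$class_label])
  keep <- vapply(seq_len(nrow(data)), function(i) {
    sum(data$class_label[-i] == data$class_label[i]) > 0L
  }, logical(1))
  if (!all(keep)) {
    warn(sprintf("skipping %d sequence(s) whose removal empties their class",
                 sum(!keep)))
  }
  idx <- which(keep)
  preds <- purrr::map_dbl(idx, function(i) {
    fit <- ann_train(data[-i, ], y[-i], cfg)
    predict(fit, data[i, , drop = FALSE])
  })
  per_seq <- tibble(
    seq_id = data$seq_id[idx], class_label = data$class_label[idx],
    beta_pp = preds, expected = y[idx]
  )
  # match flag: the class whose centroid is nearest the prediction
  per_seq$nearest_class <- names(centroids)[apply(
    abs(outer(per_seq$beta_pp, centroids, "-")), 1L, which.min)]
  per_seq$matched <- per_seq$nearest_class == per_seq$class_label
  chi <- chi_squared(per_seq$beta_pp, per_seq$expected)
  structure(
    list(per_seq = per_seq, chi2 = chi$chi2, df = chi$df,
         p_value = chi$p_value, config = cfg),
    class = "gh9_loocv"
  )
}

#' @export
print.gh9_loocv <- function(x, ...) {
  cat(sprintf("<gh9 loocv> n=%d, chi2 = %.4g (df %d), %d/%d nearest-centroid matches\n",
              nrow(x$per_seq), x$chi2, x$df, sum(x$per_seq$matched),
              nrow(x$per_seq)))
  invisible(x)
}

#' Serialise a trained network to JSON
#'
#' @param model A `gh9_ann`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ann_json <- function(model, path) {
  stopifnot(inherits(model, "gh9_ann"))
  jsonlite::write_json(
    list(W = model$weights$W,
         b = model$weights$b,
         scaling = model$scaling,
         converged = model$converged, steps = model$steps,
         training_error = model$training_error,
         config = unclass(model$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
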