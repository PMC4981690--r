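# End-to-end orchestration: profile building, screening, scoring, the beta
# filter, centroid clustering, network training/validation, rule derivation or
# loading, assignment, evaluation and taxonomy summaries, with every
# intermediate written to an artifact directory.

#' Run the full classification pipeline
#'
#' Stages: (1) build the leave-one-out profile registry from the training
#' sequences; (2) score the training set against its retained leave-one-out
#' profiles and compute training beta values; (3) fit class centroids beta' by
#' k-means with outlier exclusion; (4) train the centroid-approximating
#' network on the training alpha triples and validate it leave-one-out;
#' (5) screen the query sequences with the generic profiles, score the
#' candidates against the class profiles, and compute their beta table;
#' (6) predict beta'' for the candidates; (7) derive interval rules from the
#' well-screened candidates (or load a supplied rule table) and assign
#' classes; (8) evaluate assignments against the maximum-mean reference labels
#' per screening partition and summarise per organism.
#'
#' @param train Tibble with `uid`, `class_label`, `residues` (and optionally
#'   `organism`) for the labelled training sequences.
#' @param query Tibble with `uid`, `residues` (and optionally `organism`) for
#'   the sequences to classify.
#' @param out_dir Artifact directory (created).
#' @param seed Integer seed governing clustering and network initialisation.
#' @param search A [search_config()].
#' @param screen A [screen_config()].
#' @param cluster A [cluster_config()]; its seed defaults to `seed`.
#' @param ann A [ann_config()]; its seed defaults to `seed`.
#' @param rules `"derive"` (derive per-class beta'' intervals from the
#'   well-screened candidates), a rule tibble, or a YAML path.
#' @return A `gh9_pipeline` list with the registry, beta tables, cluster
#'   model, network, leave-one-out validation, rules, assignments, evaluation
#'   and taxonomy, plus `out_dir`.
#' @export
run_pipeline <- function(train, query, out_dir = tempfile("gh9run_"), seed = 1L,
                         search = search_config(), screen = screen_config(),
                         cluster = cluster_config(seed = seed),
                         ann = ann_config(seed = seed),
                         rules = "derive") {
  stopifnot(all(c("uid", "class_label", "residues") %in% names(train)))
  stopifnot(all(c("uid", "residues") %in% names(query)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  log_lines <- c(
    sprintf("gh9class %s", as.character(packageVersion("gh9class"))),
    sprintf("R %s", as.character(getRversion())),
    sprintf("seed %d", seed),
    sprintf("config hash %s", rlang::hash(list(search, screen, cluster, ann, rules))),
    sprintf("n_train %d  n_query %d", nrow(train), nrow(query))
  )

  registry <- stage("build-profiles",
                    build_loocv_registry(train, file.path(out_dir, "registry")))

  train_scores <- stage("score-training", score_profiles(train, registry, search))
  write_gh9_tsv(train_scores, file.path(out_dir, "train_scores.tsv"), seed, search)
  train_beta <- stage("beta-training", {
    members <- score_members(train_scores, registry, mode = "loocv")
    beta_table(members, screen)
  })
  train_beta <- left_join(train_beta,
                          select(train, seq_id = "uid", "class_label"),
                          by = "seq_id")
  write_gh9_tsv(train_beta, file.path(out_dir, "train_beta.tsv"), seed, screen)

  centroids <- stage("cluster", fit_centroids(train_beta, cluster))
  write_cluster_json(centroids, file.path(out_dir, "cluster.json"))

  kept <- dplyr::filter(train_beta, !.data$seq_id %in% centroids$excluded_uids)
  net <- stage("train-ann",
               ann_train(kept, unname(centroids$centroids[kept$class_label]), ann))
  write_ann_json(net, file.path(out_dir, "ann.json"))
  loocv <- stage("loocv", ann_loocv(kept, centroids, ann))
  write_gh9_tsv(loocv$per_seq, file.path(out_dir, "loocv.tsv"), seed, ann)

  candidates <- stage("screen-homologs", {
    faa <- file.path(out_dir, "query.faa")
    write_fasta(query, faa)
    screen_homologs(faa, registry, search)
  })
  query_kept <- dplyr::filter(query, .data$uid %in% candidates)
  if (nrow(query_kept) == 0L) abort("no query sequences survive the generic homolog screen")

  query_scores <- stage("score-query", score_profiles(query_kept, registry, search))
  write_gh9_tsv(query_scores, file.path(out_dir, "query_scores.tsv"), seed, search)
  query_beta <- stage("beta-query", {
    members <- score_members(query_scores, registry, mode = "generic")
    beta_table(members, screen)
  })
  write_gh9_tsv(query_beta, file.path(out_dir, "query_beta.tsv"), seed, screen)

  query_beta$beta_pp <- stage("predict", predict(net, query_beta))
  betapp <- select(query_beta, "seq_id", "beta_pp", alpha13 = "a13",
                   "partition", "well_spaced", "max_class")
  write_gh9_tsv(betapp, file.path(out_dir, "betapp.tsv"), seed, ann)

  rule_tbl <- stage("rules", {
    if (is.character(rules) && length(rules) == 1L && rules == "derive") {
      calib <- dplyr::filter(betapp, .data$well_spaced, .data$max_class %in% CLASS_LABELS)
      if (nrow(calib) < 3L) abort("too few well-screened candidates to derive rules")
      derive_rules(calib$beta_pp, calib$max_class)
    } else if (is.character(rules)) {
      read_rules_yaml(rules)
    } else {
      validate_rules(rules)
    }
  })
  write_rules_yaml(rule_tbl, file.path(out_dir, "rules.yaml"))

  assignments <- stage("classify", assign_class(betapp, rule_tbl))
  if ("organism" %in% names(query)) {
    assignments <- left_join(assignments,
                             select(query, seq_id = "uid", "organism"),
                             by = "seq_id")
  }
  write_gh9_tsv(assignments, file.path(out_dir, "classes.tsv"), seed, rule_tbl)

  evaluable <- dplyr::filter(betapp, .data$max_class %in% CLASS_LABELS)
  evaluation <- stage("evaluate", evaluate_assignments(
    select(dplyr::filter(assignments, .data$seq_id %in% evaluable$seq_id),
           "seq_id", "label"),
    select(evaluable, "seq_id", reference = "max_class"),
    select(query_beta, "seq_id", "partition", "d_ab", "d_bc", "d_ac")
  ))
  write_gh9_tsv(evaluation, file.path(out_dir, "evaluation.tsv"), seed, rule_tbl)

  taxonomy <- if ("organism" %in% names(assignments)) {
    tx <- summarize_taxonomy(assignments)
    write_gh9_tsv(tx, file.path(out_dir, "taxonomy.tsv"), seed, rule_tbl)
    tx
  } else NULL

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  structure(
    list(registry = registry, train_beta = train_beta, centroids = centroids,
         ann = net, loocv = loocv, query_beta = query_beta, rules = rule_tbl,
         assignments = assignments, evaluation = evaluation,
         taxonomy = taxonomy, out_dir = out_dir, seed = seed),
    class = "gh9_pipeline"
  )
}

#' @export
print.gh9_pipeline <- function(x, ...) {
  cat(sprintf("<gh9 pipeline run> %d training, %d classified sequences\n",
              nrow(x$train_beta), nrow(x$assignments)))
  print(x$centroids)
  cat(sprintf("loocv chi2 = %.4g (df %d)\n", x$loocv$chi2, x$loocv$df))
  cat("artifacts:", x$out_dir, "\n")
  invisible(x)
}
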