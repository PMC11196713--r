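#' Pipeline configuration
#'
#' Single configuration object for the end-to-end analysis. Input is either
#' a synthetic-cohort configuration or a directory of cohort CSVs; every
#' stage seed is derived deterministically from `master_seed`, so one seed
#' reproduces the whole run.
#'
#' @param cohort A [cohort_config()] (synthetic mode) or a directory path
#'   (files mode).
#' @param k Number of phenotype clusters; `NULL` uses the index-vote
#'   winner.
#' @param k_range Candidate k values for [select_k()].
#' @param n_bootstrap Bootstrap resamples for cluster stability.
#' @param scale_items Z-score functioning items before clustering.
#' @param budget A [search_budget()]; the default desk-scale profile
#'   (20,000 combinations, 5 levels) keeps a full run near 1e5 model fits —
#'   pass `search_budget(2e6, 10)` for the full-scale profile.
#' @param combo_sizes Forward-search subset sizes.
#' @param max_missing,donors,n_iterations,train_fraction Preprocessing
#'   controls.
#' @param backward_min_share Backward-consistency rule for the consensus.
#' @param master_seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            k = NULL,
                            k_range = 2:8,
                            n_bootstrap = 100L,
                            scale_items = TRUE,
                            budget = search_budget(2e4, 5L),
                            combo_sizes = 1:4,
                            max_missing = 3L,
                            donors = 5L,
                            n_iterations = 5L,
                            train_fraction = 0.8,
                            backward_min_share = 0.5,
                            master_seed = 1L) {
  mode <- if (inherits(cohort, "cohort_config")) "synthetic"
          else if (is.character(cohort)) "files"
          else abort("`cohort` must be a cohort_config or a directory path")
  structure(as.list(environment()), class = "pipeline_config")
}

load_pipeline_cohort <- function(config) {
  if (config$mode == "synthetic") {
    cc <- config$cohort
    cc$seed <- stage_seed(config$master_seed, "cohort")
    generate_cohort(cc)
  } else {
    read_cohort(config$cohort)
  }
}

#' Objective I: define the functional phenotypes
#'
#' Index-vote selection of k, Ward clustering at the chosen (or forced) k,
#' bootstrap Jaccard stability, and Promax-rotated principal components of
#' the functioning items. The resulting cluster labels are the phenotype
#' assignment passed downstream as the classification target.
#'
#' @param cohort An `fp_cohort`.
#' @param config A [pipeline_config()].
#' @return An object of class `fp_objective1`: `k_selection`, `clusters`,
#'   `stability`, `components`, `labels` tibble (participant_id,
#'   phenotype), and the cluster-by-component mean table.
#' @export
run_objective1 <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "fp_cohort"))
  items <- cohort$functioning
  if (anyNA(as.matrix(items[, -1L]))) {
    abort("objective 1 requires a complete functioning table")
  }
  seed <- config$master_seed
  ksel <- select_k(items, k_range = config$k_range,
                   scale_items = config$scale_items,
                   seed = stage_seed(seed, "select_k"))
  k <- config$k %||% ksel$winner
  clusters <- ward_cluster(items, k, scale_items = config$scale_items)
  if (length(unique(clusters$labels$cluster)) != k) {
    abort("degenerate clustering: fewer than k non-empty clusters")
  }
  stability <- bootstrap_stability(items, k,
                                   n_bootstrap = config$n_bootstrap,
                                   seed = stage_seed(seed, "bootstrap"),
                                   scale_items = config$scale_items)
  components <- pca_components(items)
  labels <- tibble::tibble(
    participant_id = clusters$labels$participant_id,
    phenotype = clusters$labels$cluster)
  profile <- dplyr::bind_cols(
    labels["phenotype"],
    components$scores[setdiff(names(components$scores),
                              "participant_id")]) |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop")
  structure(
    list(k_selection = ksel, clusters = clusters, stability = stability,
         components = components, labels = labels,
         cluster_component_means = profile),
    class = "fp_objective1")
}

#' Objective II: identify biopsychosocial correlates
#'
#' Preprocessing (exclusion, PMM imputation, 80/20 split, training-anchored
#' z-scores), the two budgeted LDA subset searches, the two one-vs-rest
#' lasso validations (cluster 3 vs rest and cluster 2 vs rest, the analogs
#' of LD1 and LD2), and the cross-method consensus with the final
#' full-sample LDA.
#'
#' @param cohort An `fp_cohort`.
#' @param labels Tibble (`participant_id`, `phenotype`), e.g. from
#'   [run_objective1()]; defaults to the cohort's true clusters.
#' @param config A [pipeline_config()].
#' @return An object of class `fp_objective2`: preprocessing report,
#'   `backward`, `forward` traces, `lasso` fits, and the `consensus`.
#' @export
run_objective2 <- function(cohort, labels = NULL,
                           config = pipeline_config()) {
  stopifnot(inherits(cohort, "fp_cohort"))
  seed <- config$master_seed
  if (is.null(labels)) {
    labels <- tibble::tibble(
      participant_id = cohort$participants$participant_id,
      phenotype = cohort$participants$true_cluster)
  }
  prep <- preprocess_cohort(cohort, max_missing = config$max_missing,
                            donors = config$donors,
                            n_iterations = config$n_iterations,
                            train_fraction = config$train_fraction,
                            seed = stage_seed(seed, "preprocess"))
  y_of <- function(tbl) {
    labels$phenotype[match(tbl$participant_id, labels$participant_id)]
  }
  ytr <- y_of(prep$train)
  yte <- y_of(prep$test)
  if (anyNA(ytr) || anyNA(yte)) {
    abort("every retained participant needs a phenotype label")
  }
  p_free <- ncol(prep$train) - 1L
  sizes <- config$combo_sizes[vapply(config$combo_sizes, function(s) {
    count_combinations(p_free, s) <= config$budget$max_combinations
  }, TRUE)]
  if (!identical(sizes, config$combo_sizes)) {
    message("forward combo sizes trimmed to the budget: ",
            paste(sizes, collapse = ", "))
  }
  backward <- backward_eliminate(prep$train, ytr, prep$test, yte,
                                 budget = config$budget)
  # the 3-of-4 fixing rule shrinks with the number of sizes actually run
  forward <- forward_select(prep$train, ytr, prep$test, yte,
                            budget = config$budget, combo_sizes = sizes,
                            consistency_threshold = min(3L, length(sizes)))
  lasso <- lapply(c(3L, 2L), function(target) {
    fit_ovr_lasso(prep$train, ytr, prep$test, yte, target_cluster = target,
                  seed = stage_seed(seed, paste0("lasso", target)))
  })
  # final model: full-sample z-scores (the model describes the whole sample)
  full_raw <- dplyr::bind_rows(prep$train, prep$test)
  full_std <- standardize_predictors(full_raw)$train
  y_full <- y_of(full_std)
  consensus <- build_consensus(backward, forward, lasso, full_std, y_full,
                               backward_min_share = config$backward_min_share)
  structure(
    list(preprocess = prep, backward = backward, forward = forward,
         lasso = lasso, consensus = consensus,
         labels_used = labels),
    class = "fp_objective2")
}

#' Run the full pipeline from one configuration
#'
#' Objective I (phenotype definition) feeds its cluster labels into
#' Objective II (correlate identification); all stage seeds derive from
#' the configuration's master seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `fp_pipeline`: the cohort, both objective
#'   bundles, and the rendered report.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- load_pipeline_cohort(config)
  obj1 <- run_objective1(cohort, config)
  obj2 <- run_objective2(cohort, labels = obj1$labels, config = config)
  bundle <- structure(
    list(cohort = cohort, objective1 = obj1, objective2 = obj2,
         config = config),
    class = "fp_pipeline")
  bundle$report <- render_report(bundle)
  bundle
}

#' @export
print.fp_pipeline <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}

fmt_tbl <- function(tbl, digits = 3) {
  tbl <- as.data.frame(tbl)
  num <- vapply(tbl, is.numeric, TRUE)
  tbl[num] <- lapply(tbl[num], function(v) round(v, digits))
  paste(utils::capture.output(print(tbl, row.names = FALSE)),
        collapse = "\n")
}

#' Render the human-readable pipeline report
#'
#' One Markdown document with the pipeline's presentation shapes: the
#' index-vote histogram, cluster-by-component means, the masked loading
#' table, the search best-model tables, the final confusion matrix with
#' LD coefficients, and standardized key-correlate profiles per cluster.
#'
#' @param bundle An `fp_pipeline` (or a list with `objective1`,
#'   `objective2`, `cohort`).
#' @return Character vector of Markdown lines (class `fp_report`).
#' @export
render_report <- function(bundle) {
  o1 <- bundle$objective1
  o2 <- bundle$objective2
  if (is.null(o1) || is.null(o2)) abort("incomplete bundle")
  lines <- c("# Functional phenotype pipeline report", "")

  lines <- c(lines, "## Cluster-number vote", "",
             fmt_tbl(o1$k_selection$votes),
             sprintf("majority winner: k = %d", o1$k_selection$winner), "")

  lines <- c(lines, "## Cluster stability (bootstrap Jaccard)", "",
             fmt_tbl(o1$stability$stability), "")

  lines <- c(lines, "## Cluster-by-component mean scores", "",
             fmt_tbl(o1$cluster_component_means), "")

  lines <- c(lines, "## Rotated component loadings (|loading| < 0.3 masked)",
             "", fmt_tbl(mask_loadings(o1$components)), "")

  lines <- c(lines, "## Search best models", "", "### Backward elimination",
             "", fmt_tbl(best_models_report(o2$backward)), "",
             "### Forward selection", "",
             fmt_tbl(best_models_report(o2$forward)), "")

  cons <- o2$consensus
  if (length(cons$key_correlates)) {
    co <- cons$final_model$scaling
    lines <- c(lines, "## Final consensus model", "",
               sprintf("key correlates: %s",
                       paste(cons$key_correlates, collapse = ", ")), "",
               "confusion matrix (actual x predicted):",
               fmt_tbl(as.data.frame.matrix(cons$final_metrics$confusion)),
               sprintf("accuracy: %.3f; balanced accuracy: %.3f",
                       cons$final_metrics$accuracy,
                       cons$final_metrics$balanced_accuracy), "",
               "LD coefficients:",
               fmt_tbl(tibble::as_tibble(co, rownames = "predictor")), "")
    # standardized profiles of the key correlates per phenotype
    labs <- o2$labels_used
    X <- bundle$cohort$predictors
    prof <- purrr::map_dfr(cons$key_correlates, function(nm) {
      v <- scale(X[[nm]])[, 1L]
      ph <- labs$phenotype[match(X$participant_id, labs$participant_id)]
      keep <- !is.na(v) & !is.na(ph)
      tibble::tibble(predictor = nm,
                     phenotype = sort(unique(ph[keep])),
                     mean_z = tapply(v[keep], ph[keep], mean))
    })
    lines <- c(lines, "## Key-correlate standardized profiles", "",
               fmt_tbl(tidyr::pivot_wider(prof, names_from = "phenotype",
                                          values_from = "mean_z",
                                          names_prefix = "cluster_")), "")
  } else {
    lines <- c(lines, "## Final consensus model", "",
               "no consensus: the backward and forward selections do not",
               "intersect; per-method sets:",
               sprintf("backward: %s",
                       paste(cons$backward_set, collapse = ", ")),
               sprintf("forward: %s",
                       paste(cons$forward_set, collapse = ", ")), "")
  }
  structure(lines, class = "fp_report")
}

#' @export
print.fp_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
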