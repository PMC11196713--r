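#' One-vs-rest lasso validation model
#'
#' L1-penalized binomial regression of one phenotype cluster against the
#' rest, with the penalty chosen at the minimum mean cross-validated
#' deviance. The predictors with nonzero L1 coefficients are recorded and
#' refit with a ridge penalty on the full sample (see [ridge_refit()]) so
#' every selected predictor retains a reportable coefficient. Accuracies
#' use the 0.5 posterior threshold; note the two-class chance level is 50%,
#' against 33% for the three-class discriminant models.
#'
#' @param train_x,train_y Standardized training predictors and cluster
#'   labels.
#' @param test_x,test_y Hold-out split.
#' @param target_cluster The cluster coded 1 in the one-vs-rest contrast.
#' @param n_folds Cross-validation folds for the penalty path (default 10).
#' @param seed Seed for the fold assignment.
#' @return An object of class `fp_ovr`: `target_cluster`,
#'   `lambda_selected`, `selected_predictors`, `refit_coefficients`
#'   (tibble), `train_accuracy`, `test_accuracy`, `chance_level` (0.5).
#' @export
fit_ovr_lasso <- function(train_x, train_y, test_x, test_y, target_cluster,
                          n_folds = 10L, seed = 1L) {
  Xtr <- as_item_matrix(as.data.frame(train_x))
  Xte <- as_item_matrix(as.data.frame(test_x))
  ytr <- as.integer(train_y == target_cluster)
  yte <- as.integer(test_y == target_cluster)
  if (length(unique(ytr)) < 2L) {
    abort("both classes of the binarized problem must be non-empty")
  }
  foldid <- with_seed(seed, sample(rep(seq_len(n_folds),
                                       length.out = nrow(Xtr))))
  cvfit <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 1,
                             foldid = foldid, type.measure = "deviance",
                             standardize = FALSE)
  lam <- cvfit$lambda.min
  beta <- as.matrix(coef(cvfit, s = "lambda.min"))
  selected <- rownames(beta)[-1L][beta[-1L, 1L] != 0]

  acc <- function(X, y) {
    p <- predict(cvfit, newx = X, s = "lambda.min", type = "response")
    mean(as.integer(p > 0.5) == y)
  }
  refit <- if (length(selected)) {
    X_full <- rbind(Xtr, Xte)
    y_full <- c(ytr, yte)
    ridge_refit(X_full, y_full, selected, seed = seed)
  } else NULL

  structure(
    list(target_cluster = target_cluster,
         lambda_selected = lam,
         selected_predictors = selected,
         lasso_coefficients = tibble::tibble(
           predictor = rownames(beta)[-1L],
           coefficient = unname(beta[-1L, 1L])),
         refit_coefficients = refit,
         train_accuracy = acc(Xtr, ytr),
         test_accuracy = acc(Xte, yte),
         chance_level = 0.5),
    class = "fp_ovr")
}

#' @export
print.fp_ovr <- function(x, ...) {
  cat(sprintf(
    "<fp_ovr> cluster %s vs rest: lambda %.4g, %d predictors selected\n",
    x$target_cluster, x$lambda_selected, length(x$selected_predictors)))
  cat(sprintf("  train accuracy %.3f, test accuracy %.3f (chance %.2f)\n",
              x$train_accuracy, x$test_accuracy, x$chance_level))
  invisible(x)
}

#' Ridge refit of L1-selected predictors
#'
#' L2-penalized binomial fit restricted to the selected predictors, with a
#' small penalty chosen by cross-validation, so all selected predictors
#' retain nonzero coefficients for reporting (the L1 fit would shrink some
#' exactly to zero). Predictors are used unstandardized by the penalty
#' (inputs are already z-scored).
#'
#' @param x Full-sample predictor matrix or data frame.
#' @param y_binarized 0/1 outcome of the one-vs-rest contrast.
#' @param selected_predictors Non-empty character vector of column names.
#' @param n_folds,seed Cross-validation controls for the penalty.
#' @return Tibble `predictor`, `coefficient` (plus the intercept row), with
#'   attribute `lambda`.
#' @export
ridge_refit <- function(x, y_binarized, selected_predictors,
                        n_folds = 10L, seed = 1L) {
  if (!length(selected_predictors)) abort("empty selection")
  X <- as_item_matrix(as.data.frame(x))
  missing_cols <- setdiff(selected_predictors, colnames(X))
  if (length(missing_cols)) {
    abort(paste0("unknown predictors: ", paste(missing_cols, collapse = ", ")))
  }
  Xs <- X[, selected_predictors, drop = FALSE]
  pad <- ncol(Xs) == 1L  # glmnet needs >= 2 columns; pad with a null column
  if (pad) Xs <- cbind(Xs, `..pad..` = 0)
  foldid <- with_seed(seed, sample(rep(seq_len(n_folds),
                                       length.out = nrow(Xs))))
  cvfit <- glmnet::cv.glmnet(Xs, y_binarized, family = "binomial",
                             alpha = 0, foldid = foldid,
                             standardize = FALSE)
  beta <- as.matrix(coef(cvfit, s = "lambda.min"))
  out <- tibble::tibble(predictor = rownames(beta),
                        coefficient = unname(beta[, 1L]))
  if (pad) out <- out[out$predictor != "..pad..", ]
  attr(out, "lambda") <- cvfit$lambda.min
  out
}

#' Consensus of the three selection strategies and final model
#'
#' Key correlates are the predictors fixed by the forward search that are
#' also consistently present in the backward search's level-best models
#' (membership in at least `backward_min_share` of the levels). The lasso
#' selections are reported for corroboration only. A final LDA on the full
#' standardized sample, restricted to the key correlates, provides the
#' unified summary: coefficients, confusion matrix, accuracy and balanced
#' accuracy.
#'
#' @param backward_trace,forward_trace `fp_search_trace` objects.
#' @param lasso_fits List of `fp_ovr` fits (corroboration).
#' @param x_full,y_full Full-sample standardized predictors and phenotype
#'   labels for the final model.
#' @param backward_min_share Consistency rule for the backward set
#'   (default 0.5).
#' @return An object of class `fp_consensus`: per-method predictor sets,
#'   `key_correlates`, `final_model` (`fp_lda` or `NULL` if the
#'   intersection is empty), `final_metrics`.
#' @export
build_consensus <- function(backward_trace, forward_trace, lasso_fits,
                            x_full, y_full, backward_min_share = 0.5) {
  backward_set <- selected_predictors(backward_trace,
                                      min_share = backward_min_share)
  forward_set <- selected_predictors(forward_trace)
  key <- forward_set[forward_set %in% backward_set]  # forward fixing order
  lasso_sets <- lapply(lasso_fits, function(f) f$selected_predictors)
  if (!is.null(lasso_fits) && length(lasso_fits)) {
    names(lasso_sets) <- vapply(lasso_fits, function(f) {
      paste0("cluster", f$target_cluster, "_vs_rest")
    }, "")
  }
  final_model <- NULL
  final_metrics <- NULL
  if (!length(key)) {
    warning("empty intersection of backward and forward selections; ",
            "no final model fitted")
  } else {
    X <- as_item_matrix(as.data.frame(x_full))
    final_model <- fit_lda(X[, key, drop = FALSE], y_full)
    final_metrics <- evaluate_lda(final_model, X[, key, drop = FALSE],
                                  y_full)
  }
  structure(
    list(backward_set = backward_set,
         forward_set = forward_set,
         lasso_sets = lasso_sets,
         key_correlates = key,
         final_model = final_model,
         final_metrics = final_metrics),
    class = "fp_consensus")
}

#' @export
print.fp_consensus <- function(x, ...) {
  cat("<fp_consensus>\n")
  cat("  backward set:", paste(x$backward_set, collapse = ", "), "\n")
  cat("  forward set: ", paste(x$forward_set, collapse = ", "), "\n")
  cat("  key correlates:", if (length(x$key_correlates)) {
    paste(x$key_correlates, collapse = ", ")
  } else "(none)", "\n")
  if (!is.null(x$final_metrics)) {
    cat(sprintf("  final model: accuracy %.3f, balanced accuracy %.3f\n",
                x$final_metrics$accuracy,
                x$final_metrics$balanced_accuracy))
  }
  invisible(x)
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Compare a variable across phenotype clusters
#'
#' Continuous variables: all pairwise Welch t-tests with Holm step-down
#' adjustment (family = the variable's pairwise comparisons) plus a one-way
#' ANOVA overall row. Categorical variables: Fisher's exact test on the
#' cluster-by-category contingency table (exact where feasible, otherwise
#' seeded Monte-Carlo, with the method reported). Significance stars:
#' ns, *, **, ***, **** at 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param values Variable values, one per participant.
#' @param clusters Cluster labels, at least 2 clusters with 2+
#'   observations each.
#' @param kind `"continuous"` or `"categorical"`.
#' @param seed Seed for the Monte-Carlo Fisher fallback.
#' @return A tibble: `comparison`, `method`, `statistic`, `p_value`,
#'   `p_adjusted`, `stars`.
#' @export
compare_groups <- function(values, clusters,
                           kind = c("continuous", "categorical"),
                           seed = 1L) {
  kind <- match.arg(kind)
  clusters <- factor(clusters)
  if (nlevels(clusters) < 2L || any(table(clusters) < 2L)) {
    abort("need at least 2 clusters with at least 2 observations each")
  }
  if (kind == "continuous") {
    lev <- levels(clusters)
    pairs <- combn(lev, 2L)
    rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]
      b <- pairs[2L, i]
      tt <- t.test(values[clusters == a], values[clusters == b])
      tibble::tibble(comparison = paste(a, "vs", b),
                     method = "welch_t",
                     statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    })
    rows$p_adjusted <- p.adjust(rows$p_value, method = "holm")
    fit <- aov(values ~ clusters)
    a_tab <- anova(fit)
    overall <- tibble::tibble(comparison = "overall", method = "anova",
                              statistic = a_tab[["F value"]][1L],
                              p_value = a_tab[["Pr(>F)"]][1L],
                              p_adjusted = a_tab[["Pr(>F)"]][1L])
    out <- dplyr::bind_rows(rows, overall)
  } else {
    tab <- table(clusters, values)
    ft <- tryCatch(fisher.test(tab, workspace = 2e7),
                   error = function(e) NULL)
    method <- "fisher_exact"
    if (is.null(ft)) {
      ft <- with_seed(seed, fisher.test(tab, simulate.p.value = TRUE,
                                        B = 1e5))
      method <- "fisher_montecarlo"
    }
    out <- tibble::tibble(comparison = "overall", method = method,
                          statistic = NA_real_, p_value = ft$p.value,
                          p_adjusted = ft$p.value)
  }
  out$stars <- as.character(significance_stars(out$p_adjusted))
  out
}
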