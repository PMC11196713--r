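#' Fit a multi-class linear discriminant model
#'
#' Fisher discriminants: eigenvectors of the pooled within-class covariance
#' inverse times the between-class scatter, scaled to unit pooled
#' within-class variance, with at most `classes - 1` discriminants (two for
#' the three phenotype clusters). Classification uses the equivalent
#' equal-covariance Gaussian rule with log-prior adjustment. Discriminant
#' signs are normalized so each LD's largest-magnitude coefficient is
#' positive (the raw sign is arbitrary and would break comparisons across
#' runs).
#'
#' @param x Numeric matrix or data frame of predictors (z-scored;
#'   a `participant_id` column is dropped), n rows.
#' @param y Class labels (coercible to factor), at least 2 observations
#'   per class; requires `n > p + classes`.
#' @param priors Class prior probabilities; default empirical class
#'   proportions.
#' @return An object of class `fp_lda` with class means, pooled covariance,
#'   priors, and `scaling` (p x (classes - 1) discriminant coefficients).
#' @export
fit_lda <- function(x, y, priors = NULL) {
  X <- as_item_matrix(as.data.frame(x))
  y <- factor(y)
  n <- nrow(X)
  p <- ncol(X)
  K <- nlevels(y)
  if (any(table(y) < 2L)) abort("each class needs at least 2 observations")
  if (n <= p + K) {
    abort(sprintf("ill-posed: n = %d must exceed p + classes = %d",
                  n, p + K))
  }
  ng <- as.vector(table(y))
  if (is.null(priors)) priors <- ng / n
  if (abs(sum(priors) - 1) > 1e-8) abort("priors must sum to 1")

  M <- do.call(rbind, lapply(levels(y), function(g) {
    colMeans(X[y == g, , drop = FALSE])
  }))
  rownames(M) <- levels(y)
  S <- crossprod(X) - crossprod(sqrt(ng) * M)
  W <- S / (n - K)  # pooled within-class covariance
  sing <- which(diag(W) <= .Machine$double.eps)
  ok <- TRUE
  Winv <- tryCatch(solve(W), error = function(e) {ok <<- FALSE; NULL})
  if (!ok || length(sing)) {
    abort(paste0("singular pooled covariance",
                 if (length(sing)) paste0(" (zero-variance columns: ",
                   paste(colnames(X)[sing], collapse = ", "), ")")))
  }
  gm <- colSums(ng * M) / n
  B <- crossprod(sqrt(ng) * sweep(M, 2, gm)) / (n - K)

  # symmetric reduction: W = R'R, solve R^-T B R^-1
  Rc <- chol(W)
  Csym <- t(solve(t(Rc), t(solve(t(Rc), B))))
  es <- eigen((Csym + t(Csym)) / 2, symmetric = TRUE)
  n_ld <- min(K - 1L, p)
  scaling <- backsolve(Rc, es$vectors[, seq_len(n_ld), drop = FALSE])
  # unit pooled within-class variance (a' W a = 1) holds by construction;
  # normalize signs: largest-|coefficient| positive per LD
  signs <- vapply(seq_len(n_ld), function(j) {
    v <- scaling[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, 0)
  scaling <- sweep(scaling, 2, signs, "*")
  dimnames(scaling) <- list(colnames(X), paste0("LD", seq_len(n_ld)))

  structure(
    list(class_labels = levels(y),
         counts = ng,
         class_means = M,
         pooled_covariance = W,
         pooled_covariance_inv = Winv,
         priors = as.vector(priors),
         scaling = scaling,
         svd_values = es$values[seq_len(n_ld)],
         n = n, p = p),
    class = "fp_lda")
}

#' Predict phenotype classes from an LDA model
#'
#' @param object An `fp_lda` model.
#' @param newdata Predictor matrix/data frame with the model's columns.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.fp_lda <- function(object, newdata, ...) {
  X <- as_item_matrix(as.data.frame(newdata))
  X <- X[, rownames(object$scaling), drop = FALSE]
  A <- object$pooled_covariance_inv
  M <- object$class_means
  delta <- X %*% A %*% t(M) -
    matrix(0.5 * diag(M %*% A %*% t(M)), nrow(X), nrow(M), byrow = TRUE) +
    matrix(log(object$priors), nrow(X), nrow(M), byrow = TRUE)
  factor(object$class_labels[max.col(delta, ties.method = "first")],
         levels = object$class_labels)
}

#' Discriminant scores (projections onto the LDs)
#'
#' @param model An `fp_lda` model.
#' @param newdata Predictors.
#' @return Tibble of LD scores, centered at the grand mean of the training
#'   classes.
#' @export
lda_scores <- function(model, newdata) {
  X <- as_item_matrix(as.data.frame(newdata))
  X <- X[, rownames(model$scaling), drop = FALSE]
  gm <- colSums(model$counts * model$class_means) / model$n
  tibble::as_tibble(sweep(X, 2, gm) %*% model$scaling)
}

#' Leave-one-out cross-validated LDA accuracy
#'
#' Each observation is predicted from a model fit on the remaining n - 1
#' (empirical priors recomputed per fold). The implementation downdates the
#' pooled scatter by rank one per fold; the result is identical to a naive
#' refit loop.
#'
#' @param x Predictors (z-scored matrix or data frame).
#' @param y Class labels.
#' @return Proportion of correctly predicted held-out observations.
#' @export
loocv_accuracy <- function(x, y) {
  X <- as_item_matrix(as.data.frame(x))
  y <- factor(y)
  res <- cpp_lda_subset_search(
    X, as.integer(y), matrix(0, 0, ncol(X)), integer(0),
    matrix(0:(ncol(X) - 1L), nrow = 1L), nlevels(y))
  acc <- res[1L, 1L]
  if (is.nan(acc)) abort("ill-posed leave-one-out fold (singular scatter)")
  acc
}

#' Classification metrics from a fitted model
#'
#' Confusion matrix, accuracy (proportion of correct classifications) and
#' balanced accuracy (the mean of the per-class recalls).
#'
#' @param model An `fp_lda` model.
#' @param x,y Evaluation predictors and true labels (labels must be in the
#'   model's class set).
#' @return An object of class `fp_metrics`: `confusion` (actual x
#'   predicted counts), `accuracy`, `balanced_accuracy`,
#'   `per_class_recall`.
#' @export
evaluate_lda <- function(model, x, y) {
  y <- factor(y, levels = model$class_labels)
  if (anyNA(y)) abort("labels outside the model's class set")
  pred <- predict(model, x)
  classification_metrics(y, pred)
}

# Metrics from actual/predicted factors on a shared level set.
classification_metrics <- function(actual, predicted) {
  confusion <- table(actual = actual, predicted = predicted)
  recall <- diag(confusion) / rowSums(confusion)
  structure(
    list(confusion = confusion,
         accuracy = sum(diag(confusion)) / sum(confusion),
         balanced_accuracy = mean(recall),
         per_class_recall = recall),
    class = "fp_metrics")
}

#' @export
print.fp_metrics <- function(x, ...) {
  cat(sprintf("<fp_metrics> accuracy %.3f, balanced accuracy %.3f\n",
              x$accuracy, x$balanced_accuracy))
  print(x$confusion)
  invisible(x)
}

#' @export
print.fp_lda <- function(x, ...) {
  cat(sprintf("<fp_lda> %d classes, %d predictors, %d discriminants\n",
              length(x$class_labels), x$p, ncol(x$scaling)))
  print(round(x$scaling, 3))
  invisible(x)
}
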