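#' Principal components of functioning items
#'
#' Eigen-decomposition of the item correlation matrix (items are on
#' heterogeneous scales, so the correlation rather than covariance matrix
#' is used). The number of retained components defaults to Kaiser's
#' criterion (eigenvalues greater than 1); unrotated loadings are
#' eigenvectors scaled by the square root of their eigenvalue, and the
#' retained components are Promax-rotated toward oblique simple structure.
#'
#' @param items Participants x items data frame or matrix; no missing
#'   values, at least 2 items.
#' @param n_components Number of components to retain; `NULL` (default)
#'   applies Kaiser's criterion.
#' @param promax_power Power of the Promax target (default 4).
#' @return An object of class `fp_components`: `eigenvalues`,
#'   `n_components`, unrotated `loadings`, Promax `pattern` loadings,
#'   `factor_correlations`, `variance_explained` (per unrotated component,
#'   eigenvalue / n items), `scores` (regression-method component scores,
#'   see [component_scores()]) and the standardization used.
#' @export
pca_components <- function(items, n_components = NULL, promax_power = 4) {
  X <- as_item_matrix(items)
  if (anyNA(X)) abort("items must not contain missing values")
  if (ncol(X) < 2L) abort("need at least 2 items")
  if (any(apply(X, 2, sd) == 0)) abort("constant item: zero variance")
  R <- cor(X)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  if (is.null(n_components)) {
    n_components <- sum(ev > 1)
    if (n_components < 1L) {
      abort(paste0("Kaiser's criterion retains no component ",
                   "(no eigenvalue > 1); pass `n_components` explicitly"))
    }
  }
  n_components <- as.integer(n_components)
  if (n_components > ncol(X)) abort("more components than items")
  load_un <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_components)]), n_components)
  dimnames(load_un) <- list(colnames(X),
                            paste0("PC", seq_len(n_components)))
  rot <- if (n_components >= 2L) {
    promax_rotate(load_un, power = promax_power)
  } else {
    list(pattern = load_un,
         factor_correlations = diag(1))
  }
  sol <- structure(
    list(eigenvalues = ev,
         n_components = n_components,
         loadings = load_un,
         pattern = rot$pattern,
         factor_correlations = rot$factor_correlations,
         variance_explained = ev[seq_len(n_components)] / ncol(X),
         item_means = colMeans(X),
         item_sds = apply(X, 2, sd),
         items = colnames(X),
         R = R),
    class = "fp_components")
  sol$scores <- component_scores(X, sol)
  sol
}

#' Promax oblique rotation
#'
#' Normalized varimax pre-rotation followed by an oblique Procrustes fit to
#' the element-wise `|loading|^power` target with signs preserved (the
#' classical Promax procedure, via [stats::promax()]). Columns are
#' sign-normalized so each column's largest-magnitude loading is positive,
#' and ordered by their sum of squared loadings so component numbering is
#' stable.
#'
#' @param loadings Items x components matrix of unrotated loadings
#'   (at least 2 components).
#' @param power Promax power (default 4); `power = 1` leaves the target at
#'   the varimax solution, so the rotation reduces toward varimax.
#' @return List with `pattern` (rotated pattern loadings) and
#'   `factor_correlations` (symmetric, unit diagonal).
#' @export
promax_rotate <- function(loadings, power = 4) {
  stopifnot(is.matrix(loadings))
  if (ncol(loadings) < 2L) abort("need at least 2 components to rotate")
  if (qr(loadings)$rank < ncol(loadings)) {
    abort("rank-deficient loading matrix")
  }
  pm <- stats::promax(loadings, m = power)
  pattern <- unclass(pm$loadings)
  phi <- solve(crossprod(pm$rotmat))
  # sign convention: largest |loading| per column positive
  signs <- vapply(seq_len(ncol(pattern)), function(j) {
    v <- pattern[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  signs[signs == 0] <- 1
  pattern <- sweep(pattern, 2, signs, "*")
  phi <- diag(signs) %*% phi %*% diag(signs)
  # stable component order: descending sum of squared pattern loadings
  ord <- order(colSums(pattern^2), decreasing = TRUE)
  pattern <- pattern[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  dimnames(phi) <- NULL
  colnames(pattern) <- paste0("PC", seq_len(ncol(pattern)))
  rownames(pattern) <- rownames(loadings)
  list(pattern = pattern, factor_correlations = phi)
}

#' Masked loading table for display
#'
#' Reporting view of a pattern matrix: absolute loadings below `threshold`
#' are blanked, and each row's largest-magnitude loading is flagged as the
#' item's primary component.
#'
#' @param pattern Items x components pattern matrix (or an
#'   `fp_components` object).
#' @param threshold Masking threshold on `|loading|` (default 0.3).
#' @return A tibble: `item`, then one character column per component
#'   (blank, `"0.62"`, or `"*0.91*"` for the primary loading), plus
#'   `primary` (component name of the largest absolute loading).
#' @export
mask_loadings <- function(pattern, threshold = 0.3) {
  if (inherits(pattern, "fp_components")) pattern <- pattern$pattern
  stopifnot(is.matrix(pattern))
  comp <- colnames(pattern) %||% paste0("PC", seq_len(ncol(pattern)))
  out <- tibble::tibble(item = rownames(pattern) %||%
                          as.character(seq_len(nrow(pattern))))
  prim <- apply(abs(pattern), 1, which.max)
  for (j in seq_along(comp)) {
    cell <- ifelse(abs(pattern[, j]) < threshold, "",
                   sprintf("%.2f", pattern[, j]))
    cell <- ifelse(prim == j & cell != "", paste0("*", cell, "*"), cell)
    out[[comp[j]]] <- unname(cell)
  }
  out$primary <- comp[prim]
  out
}

#' Component scores for participants
#'
#' Regression-method scores on standardized items: weights are
#' `R^-1 S` with `S` the structure matrix (pattern times factor
#' correlations), and score columns are rescaled to unit variance. Columns
#' are oriented so the summed item loading is positive — higher scores
#' mean better functioning, matching the orientation of the generator's
#' items.
#'
#' @param items Participants x items data (same items the solution was
#'   fitted on).
#' @param solution An `fp_components` object.
#' @return Tibble of scores, one column per component (plus
#'   `participant_id` when row names carry ids).
#' @export
component_scores <- function(items, solution) {
  stopifnot(inherits(solution, "fp_components"))
  X <- as_item_matrix(items)
  if (!setequal(colnames(X), solution$items)) {
    abort("item names do not match the fitted solution")
  }
  X <- X[, solution$items, drop = FALSE]
  Z <- sweep(sweep(X, 2, solution$item_means), 2, solution$item_sds, "/")
  R <- cor_from_loadings(solution)
  S <- solution$pattern %*% solution$factor_correlations
  Wt <- solve(R, S)
  scores <- Z %*% Wt
  # orient: summed item loading positive per component
  orient <- sign(colSums(solution$pattern))
  orient[orient == 0] <- 1
  scores <- sweep(scores, 2, orient, "*")
  v <- diag(t(Wt) %*% R %*% Wt)  # population variance of raw scores
  scores <- sweep(scores, 2, sqrt(v), "/")
  colnames(scores) <- colnames(solution$pattern)
  out <- tibble::as_tibble(scores)
  if (!is.null(rownames(X))) {
    out <- dplyr::bind_cols(
      tibble::tibble(participant_id = rownames(X)), out)
  }
  out
}

# Item correlation matrix cached at fit time.
cor_from_loadings <- function(solution) solution$R

#' @export
print.fp_components <- function(x, ...) {
  cat(sprintf(
    "<fp_components> %d of %d components retained (Kaiser: eigenvalue > 1)\n",
    x$n_components, length(x$eigenvalues)))
  cat("eigenvalues:", paste(sprintf("%.2f", x$eigenvalues), collapse = " "),
      "\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " "),
      "\n")
  invisible(x)
}
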