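#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' @rdname tidy_funcpheno
#' @name tidy_funcpheno
#' @title Broom-style tidiers for fitted pipeline objects
#' @description `tidy()` returns the per-element results of a fitted object
#'   as a tibble; `glance()` returns a one-row model summary.
#' @param x A fitted object from this package.
#' @param ... Unused.
NULL

#' @rdname tidy_funcpheno
#' @export
tidy.fp_clusters <- function(x, ...) x$labels

#' @rdname tidy_funcpheno
#' @export
glance.fp_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$labels), distance = x$distance,
                 linkage = x$linkage)
}

#' @rdname tidy_funcpheno
#' @export
tidy.fp_kselect <- function(x, ...) x$votes

#' @rdname tidy_funcpheno
#' @export
glance.fp_kselect <- function(x, ...) {
  tibble::tibble(winner = x$winner, n_indices = nrow(x$winners),
                 k_min = min(x$k_range), k_max = max(x$k_range))
}

#' @rdname tidy_funcpheno
#' @export
tidy.fp_stability <- function(x, ...) x$stability

#' @rdname tidy_funcpheno
#' @export
glance.fp_stability <- function(x, ...) {
  tibble::tibble(n_bootstrap = x$n_bootstrap,
                 min_jaccard = min(x$stability$mean_jaccard),
                 any_dissolved = any(x$stability$dissolved))
}

#' @rdname tidy_funcpheno
#' @export
tidy.fp_components <- function(x, ...) {
  tibble::as_tibble(x$pattern, rownames = "item") |>
    tidyr::pivot_longer(-"item", names_to = "component",
                        values_to = "loading")
}

#' @rdname tidy_funcpheno
#' @export
glance.fp_components <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_items = length(x$eigenvalues),
                 variance_explained = sum(x$variance_explained))
}

#' @rdname tidy_funcpheno
#' @export
tidy.fp_lda <- function(x, ...) {
  tibble::as_tibble(x$scaling, rownames = "predictor") |>
    tidyr::pivot_longer(-"predictor", names_to = "discriminant",
                        values_to = "coefficient")
}

#' @rdname tidy_funcpheno
#' @export
glance.fp_lda <- function(x, ...) {
  tibble::tibble(n = x$n, n_predictors = x$p,
                 n_classes = length(x$class_labels),
                 n_discriminants = ncol(x$scaling))
}

#' @rdname tidy_funcpheno
#' @export
tidy.fp_metrics <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$confusion))
}

#' @rdname tidy_funcpheno
#' @export
glance.fp_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 balanced_accuracy = x$balanced_accuracy)
}

#' @rdname tidy_funcpheno
#' @export
tidy.fp_search_trace <- function(x, ...) best_models_report(x)

#' @rdname tidy_funcpheno
#' @export
glance.fp_search_trace <- function(x, ...) {
  steps <- if (x$algorithm == "backward") x$levels else x$iterations
  tibble::tibble(
    algorithm = x$algorithm,
    n_steps = length(steps),
    n_models = sum(vapply(steps, `[[`, 0, "n_models_evaluated")),
    terminated_reason = x$terminated_reason)
}

#' @rdname tidy_funcpheno
#' @export
tidy.fp_ovr <- function(x, ...) {
  if (is.null(x$refit_coefficients)) {
    return(tibble::tibble(predictor = character(), coefficient = double()))
  }
  x$refit_coefficients
}

#' @rdname tidy_funcpheno
#' @export
glance.fp_ovr <- function(x, ...) {
  tibble::tibble(target_cluster = x$target_cluster,
                 lambda = x$lambda_selected,
                 n_selected = length(x$selected_predictors),
                 train_accuracy = x$train_accuracy,
                 test_accuracy = x$test_accuracy,
                 chance_level = x$chance_level)
}

#' @rdname tidy_funcpheno
#' @export
tidy.fp_consensus <- function(x, ...) {
  all_pred <- sort(unique(c(x$backward_set, x$forward_set,
                            unlist(x$lasso_sets))))
  tibble::tibble(
    predictor = all_pred,
    in_backward = all_pred %in% x$backward_set,
    in_forward = all_pred %in% x$forward_set,
    in_lasso = all_pred %in% unlist(x$lasso_sets),
    key_correlate = all_pred %in% x$key_correlates)
}

#' @rdname tidy_funcpheno
#' @export
glance.fp_consensus <- function(x, ...) {
  tibble::tibble(
    n_key_correlates = length(x$key_correlates),
    accuracy = if (is.null(x$final_metrics)) NA_real_
               else x$final_metrics$accuracy,
    balanced_accuracy = if (is.null(x$final_metrics)) NA_real_
                        else x$final_metrics$balanced_accuracy)
}
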