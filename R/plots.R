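#' @import ggplot2
NULL

#' Plot methods
#'
#' `autoplot()` methods give the standard presentation shape of each
#' result: the index-vote histogram for k selection, per-cluster bootstrap
#' stability with the 0.5 dissolution line, a masked loading heat map,
#' cluster-by-component mean profiles, search accuracy traces, and the
#' confusion-matrix tile plot.
#'
#' @param object A fitted object from this package.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot_funcpheno
NULL

#' @rdname autoplot_funcpheno
#' @export
autoplot.fp_kselect <- function(object, ...) {
  ggplot(object$votes, aes(x = factor(.data$k), y = .data$votes)) +
    geom_col(fill = "grey30") +
    labs(x = "candidate number of clusters k",
         y = "indices preferring k",
         title = "Cluster-number index vote") +
    theme_minimal()
}

#' @rdname autoplot_funcpheno
#' @export
autoplot.fp_stability <- function(object, ...) {
  ggplot(object$stability,
         aes(x = factor(.data$cluster), y = .data$mean_jaccard)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "cluster", y = "mean bootstrap Jaccard",
         title = sprintf("Cluster stability (%d resamples)",
                         object$n_bootstrap)) +
    theme_minimal()
}

#' @rdname autoplot_funcpheno
#' @export
autoplot.fp_components <- function(object, ...) {
  df <- tidy(object)
  df$loading_masked <- ifelse(abs(df$loading) < 0.3, NA, df$loading)
  ggplot(df, aes(x = .data$component, y = .data$item,
                 fill = .data$loading_masked)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", high = "darkorange",
                         na.value = "grey95", name = "loading") +
    labs(title = "Promax pattern loadings (|loading| < 0.3 masked)") +
    theme_minimal()
}

#' @rdname autoplot_funcpheno
#' @export
autoplot.fp_objective1 <- function(object, ...) {
  df <- tidyr::pivot_longer(object$cluster_component_means,
                            -"phenotype", names_to = "component",
                            values_to = "mean_score")
  ggplot(df, aes(x = .data$component, y = .data$mean_score,
                 fill = factor(.data$phenotype))) +
    geom_col(position = "dodge") +
    labs(x = "functioning component", y = "mean component score",
         fill = "phenotype",
         title = "Phenotype profiles across functioning components") +
    theme_minimal()
}

#' @rdname autoplot_funcpheno
#' @export
autoplot.fp_search_trace <- function(object, ...) {
  df <- best_models_report(object)
  df <- tidyr::pivot_longer(df, dplyr::all_of(c("train_accuracy",
                                                "test_accuracy")),
                            names_to = "split", values_to = "accuracy")
  ggplot(df, aes(x = .data$step, y = .data$accuracy,
                 colour = .data$split)) +
    geom_line() + geom_point() +
    labs(x = if (object$algorithm == "backward") "level" else "iteration",
         y = "best-model accuracy",
         title = sprintf("%s search accuracy trace", object$algorithm)) +
    theme_minimal()
}

#' @rdname autoplot_funcpheno
#' @export
autoplot.fp_metrics <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$predicted, y = .data$actual,
                 fill = .data$Freq)) +
    geom_tile() +
    geom_text(aes(label = .data$Freq)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(title = sprintf("Confusion matrix (accuracy %.2f, balanced %.2f)",
                         object$accuracy, object$balanced_accuracy)) +
    theme_minimal()
}
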