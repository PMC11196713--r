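#' Exact binomial coefficient
#'
#' Computed with the multiplicative formula so every intermediate value is
#' an exact integer; exact for results below 2^53 (the search sizes here
#' top out near 1.8e11).
#'
#' @param n,k Non-negative integers with `k <= n`.
#' @return `choose(n, k)` as an exact double.
#' @export
count_combinations <- function(n, k) {
  if (k < 0 || n < 0) abort("`n` and `k` must be non-negative")
  if (k > n) abort("`k` must not exceed `n`")
  k <- min(k, n - k)
  res <- 1
  for (i in seq_len(k)) res <- res * (n - k + i) / i
  round(res)
}

#' Search budget for the subset searches
#'
#' @param max_combinations Largest number of candidate subsets evaluated at
#'   any one level (default 2,000,000).
#' @param max_level Largest subset size examined by the backward search
#'   (default 10).
#' @return A `search_budget` list.
#' @export
search_budget <- function(max_combinations = 2e6, max_level = 10L) {
  if (max_combinations < 1 || max_level < 1) {
    abort("budget components must be at least 1")
  }
  structure(list(max_combinations = max_combinations,
                 max_level = as.integer(max_level)),
            class = "search_budget")
}

#' Eliminations needed to fit a level within budget
#'
#' The smallest `m >= 0` such that `C(pool_size - m, k)` does not exceed
#' the combination budget.
#'
#' @param pool_size Current predictor-pool size.
#' @param k Subset size of the level.
#' @param budget Maximum number of combinations allowed.
#' @return Integer count of predictors to eliminate.
#' @export
plan_level <- function(pool_size, k, budget) {
  if (budget < 1) abort("`budget` must be at least 1")
  if (k > pool_size) abort("`k` exceeds the pool size")
  m <- 0L
  while (count_combinations(pool_size - m, k) > budget) {
    m <- m + 1L
    if (pool_size - m < k) abort("pool cannot be shrunk to fit the budget")
  }
  m
}

# Evaluate a set of predictor subsets: LOOCV accuracy on the training
# split and accuracy on the hold-out test split. `subsets` is a list of
# integer vectors (1-based indices into the predictor columns). Chunked so
# a single compiled call never holds more than 2e5 subsets.
evaluate_subsets <- function(Xtr, ytr, Xte, yte, subsets_mat, n_classes) {
  stopifnot(is.matrix(subsets_mat))
  n_sub <- nrow(subsets_mat)
  out <- matrix(NA_real_, n_sub, 2)
  chunk <- 2e5
  starts <- seq(1L, n_sub, by = chunk)
  for (s0 in starts) {
    s1 <- min(s0 + chunk - 1L, n_sub)
    out[s0:s1, ] <- cpp_lda_subset_search(
      Xtr, ytr, Xte, yte,
      subsets_mat[s0:s1, , drop = FALSE] - 1L, n_classes)
  }
  out
}

# Best model among evaluated subsets: highest score, ties by higher
# secondary accuracy, then smaller subset (sizes equal within a level),
# then lexicographically smallest sorted name string. Deterministic and
# independent of evaluation order.
best_model_index <- function(score, secondary, subsets_mat, names_all) {
  score[is.na(score)] <- -Inf
  secondary[is.na(secondary)] <- -Inf
  cand <- which(score == max(score))
  if (length(cand) > 1L) {
    cand <- cand[secondary[cand] == max(secondary[cand])]
  }
  if (length(cand) > 1L) {
    keys <- vapply(cand, function(i) {
      paste(sort(names_all[subsets_mat[i, ]]), collapse = "|")
    }, "")
    cand <- cand[order(keys)][1L]
  }
  cand[1L]
}

# Per-predictor aggregate of an accuracy vector over all subsets
# containing the predictor. Returns max and mean per predictor index.
predictor_scores <- function(subsets_mat, acc, p) {
  acc[is.na(acc)] <- -Inf
  mx <- rep(-Inf, p)
  sm <- numeric(p)
  cnt <- numeric(p)
  for (j in seq_len(ncol(subsets_mat))) {
    col <- subsets_mat[, j]
    t_mx <- tapply(acc, col, max)
    idx <- as.integer(names(t_mx))
    mx[idx] <- pmax(mx[idx], t_mx)
    t_sm <- tapply(acc, col, sum)
    sm[idx] <- sm[idx] + t_sm
    cnt[idx] <- cnt[idx] + tabulate(col, p)[idx]
  }
  list(max = mx, mean = ifelse(cnt > 0, sm / cnt, -Inf))
}

# combn() treats a length-1 numeric x as seq_len(x); guard that corner.
subsets_of <- function(pool, k) {
  if (length(pool) == 1L) {
    stopifnot(k == 1L)
    return(matrix(pool, 1L, 1L))
  }
  t(combn(pool, k))
}

prepare_xy <- function(x, y) {
  X <- as_item_matrix(as.data.frame(x))
  list(X = X, y = as.integer(factor(y)))
}

#' Budgeted backward-elimination LDA search
#'
#' For each level `k = 1..max_level`, every `k`-subset of the current
#' predictor pool is fitted by LDA on the training split (scored by
#' leave-one-out cross-validation) and evaluated on the hold-out test
#' split. Before a level whose full enumeration would exceed the
#' combination budget, the worst predictors from the previous level are
#' permanently eliminated — "worst" being lowest maximum (default; or mean)
#' accuracy over all previous-level subsets containing the predictor, ties
#' broken by lower mean accuracy then name order.
#'
#' @param train_x,train_y Standardized training predictors and phenotype
#'   labels.
#' @param test_x,test_y Hold-out split.
#' @param budget A [search_budget()].
#' @param elimination_metric `"max"` (default) or `"mean"` per-predictor
#'   aggregation for elimination ranking.
#' @param score_on `"test"` (default; scores candidate models by hold-out
#'   accuracy, as in the original procedure, at the cost of re-using the
#'   hold-out inside the search) or `"loocv"` (leakage-safe alternative).
#' @param n_best Number of top models recorded per level.
#' @return An object of class `fp_search_trace` with one record per level:
#'   candidate pool, predictors eliminated before the level, number of
#'   models evaluated (always the exact binomial count), and the ranked
#'   best models with train (LOOCV) and test accuracy.
#' @export
backward_eliminate <- function(train_x, train_y, test_x, test_y,
                               budget = search_budget(),
                               elimination_metric = c("max", "mean"),
                               score_on = c("test", "loocv"),
                               n_best = 5L) {
  elimination_metric <- match.arg(elimination_metric)
  score_on <- match.arg(score_on)
  tr <- prepare_xy(train_x, train_y)
  te <- prepare_xy(test_x, test_y)
  stopifnot(identical(colnames(tr$X), colnames(te$X)))
  nm <- colnames(tr$X)
  K <- length(unique(tr$y))
  pool <- seq_along(nm)
  levels_out <- list()
  prev_scores <- NULL
  terminated <- "max_level"

  for (k in seq_len(budget$max_level)) {
    m_elim <- plan_level(length(pool), k, budget$max_combinations)
    eliminated_here <- character(0)
    if (m_elim > 0L) {
      if (is.null(prev_scores)) {
        abort("budget too small for level 1: nothing to rank eliminations by")
      }
      keyv <- if (elimination_metric == "max") prev_scores$max
              else prev_scores$mean
      ord <- pool[order(keyv[pool], prev_scores$mean[pool], nm[pool])]
      drop_idx <- ord[seq_len(m_elim)]
      eliminated_here <- nm[drop_idx]
      pool <- setdiff(pool, drop_idx)
    }
    if (length(pool) < k) {
      terminated <- "pool_exhausted"
      break
    }
    subsets_mat <- subsets_of(pool, k)
    acc <- evaluate_subsets(tr$X, tr$y, te$X, te$y, subsets_mat, K)
    score <- if (score_on == "test") acc[, 2L] else acc[, 1L]
    secondary <- if (score_on == "test") acc[, 1L] else acc[, 2L]
    ranked <- rank_best_models(score, secondary, subsets_mat, nm, n_best,
                               acc)
    prev_scores <- predictor_scores(subsets_mat, score, length(nm))
    levels_out[[k]] <- list(
      level = k,
      pool = nm[pool],
      eliminated_here = eliminated_here,
      n_models_evaluated = nrow(subsets_mat),
      best_models = ranked)
  }
  structure(
    list(algorithm = "backward",
         levels = levels_out,
         predictor_names = nm,
         score_on = score_on,
         elimination_metric = elimination_metric,
         budget = budget,
         terminated_reason = terminated),
    class = "fp_search_trace")
}

# Ranked top-n models as a tibble.
rank_best_models <- function(score, secondary, subsets_mat, nm, n_best,
                             acc) {
  score2 <- ifelse(is.na(score), -Inf, score)
  sec2 <- ifelse(is.na(secondary), -Inf, secondary)
  keys <- vapply(seq_len(nrow(subsets_mat)), function(i) {
    paste(sort(nm[subsets_mat[i, ]]), collapse = "|")
  }, "")
  ord <- order(-score2, -sec2, keys)
  top <- head(ord, n_best)
  tibble::tibble(
    rank = seq_along(top),
    predictors = lapply(top, function(i) sort(nm[subsets_mat[i, ]])),
    train_accuracy = acc[top, 1L],
    test_accuracy = acc[top, 2L])
}

#' Iterative forward-selection LDA search with a consistency fixing rule
#'
#' Per iteration, for each subset size in `combo_sizes`, every subset of
#' the non-fixed predictors is joined with the currently fixed set, fitted
#' and scored as in [backward_eliminate()], and the single best model per
#' size is kept. A non-fixed predictor appearing in at least
#' `consistency_threshold` of those best models is "fixed" and carried into
#' all later iterations — so a predictor can be selected for its value in
#' combination even without a marginal effect. The search terminates
#' naturally when an iteration fixes nothing.
#'
#' @inheritParams backward_eliminate
#' @param combo_sizes Subset sizes examined per iteration (default 1:4);
#'   each full enumeration must fit the combination budget.
#' @param consistency_threshold Minimum number of best models a predictor
#'   must appear in to be fixed (default 3 of 4).
#' @param max_iterations Safety cap on iterations.
#' @return An `fp_search_trace` with per-iteration records and the ordered
#'   `fixed_predictors` (name, iteration fixed).
#' @export
forward_select <- function(train_x, train_y, test_x, test_y,
                           budget = search_budget(),
                           combo_sizes = 1:4,
                           consistency_threshold = 3L,
                           score_on = c("test", "loocv"),
                           max_iterations = 20L) {
  score_on <- match.arg(score_on)
  tr <- prepare_xy(train_x, train_y)
  te <- prepare_xy(test_x, test_y)
  nm <- colnames(tr$X)
  K <- length(unique(tr$y))
  fixed <- integer(0)
  fixed_iter <- integer(0)
  iters <- list()
  terminated <- "max_iterations"

  for (it in seq_len(max_iterations)) {
    free <- setdiff(seq_along(nm), fixed)
    sizes <- combo_sizes[combo_sizes <= length(free)]
    if (!length(sizes)) {
      terminated <- "pool_exhausted"
      break
    }
    n_comb <- vapply(sizes, function(s) {
      count_combinations(length(free), s)
    }, 0)
    if (any(n_comb > budget$max_combinations)) {
      terminated <- "budget"
      break
    }
    best_per_size <- list()
    n_models <- 0
    for (s in sizes) {
      subs <- subsets_of(free, s)
      if (length(fixed)) {
        subs <- cbind(subs,
                      matrix(fixed, nrow(subs), length(fixed), byrow = TRUE))
      }
      acc <- evaluate_subsets(tr$X, tr$y, te$X, te$y, subs, K)
      score <- if (score_on == "test") acc[, 2L] else acc[, 1L]
      secondary <- if (score_on == "test") acc[, 1L] else acc[, 2L]
      bi <- best_model_index(score, secondary, subs, nm)
      best_per_size[[as.character(s)]] <- list(
        size = s,
        predictors = sort(nm[subs[bi, ]]),
        new_predictors = sort(nm[setdiff(subs[bi, ], fixed)]),
        train_accuracy = acc[bi, 1L],
        test_accuracy = acc[bi, 2L])
      n_models <- n_models + nrow(subs)
    }
    tally <- table(unlist(lapply(best_per_size, `[[`, "new_predictors")))
    newly <- names(tally)[tally >= consistency_threshold]
    newly <- newly[order(-tally[newly], newly)]
    iters[[it]] <- list(
      iteration = it,
      n_models_evaluated = n_models,
      best_models = best_per_size,
      appearance_counts = tally,
      fixed_here = newly)
    if (!length(newly)) {
      terminated <- "natural"
      break
    }
    fixed <- c(fixed, match(newly, nm))
    fixed_iter <- c(fixed_iter, rep(it, length(newly)))
  }
  structure(
    list(algorithm = "forward",
         iterations = iters,
         fixed_predictors = tibble::tibble(
           predictor = nm[fixed],
           iteration_fixed = fixed_iter),
         predictor_names = nm,
         score_on = score_on,
         budget = budget,
         terminated_reason = terminated),
    class = "fp_search_trace")
}

#' Best-model table of a search trace
#'
#' One row per level (backward) or per iteration-and-size (forward): the
#' best subset with its training (LOOCV) and hold-out accuracy. Training
#' accuracy is not monotone across levels — the peak can occur mid-search.
#'
#' @param trace An `fp_search_trace`.
#' @return A tibble.
#' @export
best_models_report <- function(trace) {
  stopifnot(inherits(trace, "fp_search_trace"))
  if (trace$algorithm == "backward") {
    if (!length(trace$levels)) abort("empty search trace")
    purrr::map_dfr(trace$levels, function(lv) {
      best <- lv$best_models[1L, ]
      tibble::tibble(
        step = lv$level,
        n_models = lv$n_models_evaluated,
        n_eliminated = length(lv$eliminated_here),
        predictors = paste(best$predictors[[1L]], collapse = ", "),
        train_accuracy = best$train_accuracy,
        test_accuracy = best$test_accuracy)
    })
  } else {
    if (!length(trace$iterations)) abort("empty search trace")
    purrr::map_dfr(trace$iterations, function(itr) {
      purrr::map_dfr(itr$best_models, function(bm) {
        tibble::tibble(
          step = itr$iteration,
          size = bm$size,
          predictors = paste(bm$predictors, collapse = ", "),
          train_accuracy = bm$train_accuracy,
          test_accuracy = bm$test_accuracy)
      })
    })
  }
}

#' @export
print.fp_search_trace <- function(x, ...) {
  cat(sprintf("<fp_search_trace> %s search, terminated: %s\n",
              x$algorithm, x$terminated_reason))
  print(as.data.frame(best_models_report(x)), row.names = FALSE)
  invisible(x)
}

#' Predictors selected by a search trace
#'
#' For a forward trace, the fixed set. For a backward trace, predictors
#' present in the level-best model in at least `min_share` of the levels
#' ("consistent" membership).
#'
#' @param trace An `fp_search_trace`.
#' @param min_share Minimum share of backward levels whose best model must
#'   contain the predictor (default 0.5).
#' @return Character vector of predictor names.
#' @export
selected_predictors <- function(trace, min_share = 0.5) {
  stopifnot(inherits(trace, "fp_search_trace"))
  if (trace$algorithm == "forward") {
    return(trace$fixed_predictors$predictor)
  }
  n_lev <- length(trace$levels)
  counts <- table(unlist(lapply(trace$levels, function(lv) {
    lv$best_models$predictors[[1L]]
  })))
  sort(names(counts)[counts >= min_share * n_lev])
}
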