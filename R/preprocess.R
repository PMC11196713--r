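#' Exclude participants with too many missing predictors
#'
#' Implements the exclusion half of the exclusion-imputation strategy:
#' participants with more than `max_missing` missing predictor cells are
#' dropped; the rest are retained for imputation.
#'
#' @param predictors Tibble with `participant_id` plus numeric predictor
#'   columns, missing cells as `NA`.
#' @param max_missing Maximum tolerated number of missing cells (default 3,
#'   i.e. 4 or more missing excludes).
#' @return A list with tibbles `retained` and `excluded` and a `report`
#'   tibble (per participant: missing-cell count and status).
#' @export
filter_by_missingness <- function(predictors, max_missing = 3L) {
  stopifnot(is.data.frame(predictors),
            "participant_id" %in% names(predictors))
  X <- as.matrix(predictors[, -match("participant_id", names(predictors)),
                            drop = FALSE])
  n_miss <- rowSums(is.na(X))
  keep <- n_miss <= max_missing
  report <- tibble::tibble(
    participant_id = predictors$participant_id,
    n_missing = as.integer(n_miss),
    status = ifelse(keep, "retained", "excluded"))
  list(retained = predictors[keep, , drop = FALSE],
       excluded = predictors[!keep, , drop = FALSE],
       report = report)
}

#' Impute missing predictors by chained predictive mean matching
#'
#' Chained-equations predictive mean matching (PMM): for each column with
#' missing cells, in turn, the observed values are regressed on all other
#' (current-draw) columns; each missing entry is matched to the `donors`
#' observed rows with the closest predicted mean and one donor's observed
#' value is drawn uniformly. Sweeps repeat `n_iterations` times. Every
#' imputed value is therefore an observed value of its own column — a
#' binary column stays binary. A single completed dataset is returned.
#'
#' @param predictors Tibble with `participant_id` and numeric columns;
#'   `NA` marks missing. Call [filter_by_missingness()] first so no row has
#'   excessive missingness.
#' @param donors Donor-pool size (default 5).
#' @param n_iterations Number of chained sweeps (default 5).
#' @param seed Integer seed; imputation is deterministic given it.
#' @return The completed tibble (observed cells untouched).
#' @export
impute_pmm <- function(predictors, donors = 5L, n_iterations = 5L,
                       seed = 1L) {
  stopifnot(is.data.frame(predictors),
            "participant_id" %in% names(predictors))
  if (donors < 1L) abort("`donors` must be at least 1")
  id_col <- match("participant_id", names(predictors))
  X <- as.matrix(predictors[, -id_col, drop = FALSE])
  miss <- is.na(X)
  if (!any(miss)) return(predictors)
  if (any(colSums(!miss) == 0L)) {
    abort("column entirely missing: nothing to match against")
  }
  if (any(colSums(!miss) < donors)) {
    abort("every column needs at least `donors` observed values")
  }
  p <- ncol(X)

  X <- with_seed(seed, {
    # initial fill: column means of observed values
    for (j in seq_len(p)) {
      if (any(miss[, j])) {
        X[miss[, j], j] <- mean(X[!miss[, j], j])
      }
    }
    for (iter in seq_len(n_iterations)) {
      for (j in seq_len(p)) {
        mj <- miss[, j]
        if (!any(mj)) next
        others <- X[, -j, drop = FALSE]
        # guard against collinear/constant design: least squares via qr
        fit <- stats::lm.fit(cbind(1, others[!mj, , drop = FALSE]),
                             X[!mj, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred_all <- cbind(1, others) %*% beta
        pred_obs <- pred_all[!mj]
        obs_vals <- X[!mj, j]
        for (i in which(mj)) {
          d <- abs(pred_obs - pred_all[i])
          pool <- order(d)[seq_len(donors)]
          X[i, j] <- obs_vals[pool[[sample.int(donors, 1L)]]]
        }
      }
    }
    X
  })
  out <- predictors
  out[, -id_col] <- tibble::as_tibble(X)
  out
}

#' Random train/test split of participants
#'
#' Simple random (unstratified) split; the training set size is
#' `floor(train_fraction * n)`.
#'
#' @param participants Character vector of participant ids, or a data frame
#'   with a `participant_id` column.
#' @param train_fraction Fraction assigned to training, in (0, 1);
#'   default 0.8.
#' @param seed Integer seed.
#' @return Tibble with `participant_id` and `split` (`"train"`/`"test"`).
#' @export
split_train_test <- function(participants, train_fraction = 0.8, seed = 1L) {
  if (is.data.frame(participants)) participants <- participants$participant_id
  n <- length(participants)
  if (n < 5L) abort("need at least 5 participants to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1)")
  }
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  tibble::tibble(
    participant_id = participants,
    split = ifelse(seq_len(n) %in% idx, "train", "test"))
}

#' Standardize predictors with training-split parameters
#'
#' Each predictor is z-scored using the mean and sample (n-1) SD of the
#' training split only; the test split is transformed with those same
#' parameters, so no information leaks from the test set into the scaling.
#'
#' @param train,test Tibbles with `participant_id` plus numeric columns
#'   (test may be `NULL`).
#' @param on_zero_variance `"error"` (default) or `"drop"` for
#'   zero-variance training columns.
#' @return List with `train`, `test` (standardized tibbles) and `params`
#'   (tibble: predictor, mean, sd).
#' @export
standardize_predictors <- function(train, test = NULL,
                                   on_zero_variance = c("error", "drop")) {
  on_zero_variance <- match.arg(on_zero_variance)
  stopifnot(is.data.frame(train), "participant_id" %in% names(train))
  cols <- setdiff(names(train), "participant_id")
  Xtr <- as.matrix(train[, cols, drop = FALSE])
  mu <- colMeans(Xtr)
  s <- apply(Xtr, 2, sd)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    if (on_zero_variance == "error") {
      abort(paste0("zero-variance training column(s): ",
                   paste(cols[zero], collapse = ", ")))
    }
    cols <- cols[!zero]
    Xtr <- Xtr[, cols, drop = FALSE]
    mu <- mu[!zero]
    s <- s[!zero]
  }
  scale_tbl <- function(tbl) {
    if (is.null(tbl)) return(NULL)
    X <- as.matrix(tbl[, cols, drop = FALSE])
    Z <- sweep(sweep(X, 2, mu), 2, s, "/")
    dplyr::bind_cols(tibble::tibble(participant_id = tbl$participant_id),
                     tibble::as_tibble(Z))
  }
  list(train = scale_tbl(train),
       test = scale_tbl(test),
       params = tibble::tibble(predictor = cols, mean = unname(mu),
                               sd = unname(s)))
}

#' Run the full preprocessing chain on a cohort
#'
#' Exclusion by missingness, chained PMM imputation, 80/20 train/test split
#' and training-anchored standardization, with a summary report.
#'
#' @param cohort An `fp_cohort`.
#' @param max_missing,donors,n_iterations,train_fraction See the individual
#'   stages.
#' @param seed Master seed for this stage; sub-stage seeds are derived
#'   from it.
#' @return List with `train`, `test` (standardized predictor tibbles),
#'   `split` assignment, `params`, `labels` (true clusters of retained
#'   participants) and `report` (counts of excluded participants and
#'   imputed cells).
#' @export
preprocess_cohort <- function(cohort, max_missing = 3L, donors = 5L,
                              n_iterations = 5L, train_fraction = 0.8,
                              seed = 1L) {
  stopifnot(inherits(cohort, "fp_cohort"))
  filt <- filter_by_missingness(cohort$predictors, max_missing)
  n_imputed <- sum(is.na(as.matrix(filt$retained[, -1L])))
  complete <- impute_pmm(filt$retained, donors, n_iterations,
                         seed = stage_seed(seed, "impute"))
  split <- split_train_test(complete$participant_id, train_fraction,
                            seed = stage_seed(seed, "split"))
  tr <- complete[split$split == "train", , drop = FALSE]
  te <- complete[split$split == "test", , drop = FALSE]
  std <- standardize_predictors(tr, te)
  labels <- cohort$participants[
    match(complete$participant_id, cohort$participants$participant_id), ]
  list(train = std$train, test = std$test, split = split,
       params = std$params, labels = labels,
       report = list(
         n_input = nrow(cohort$predictors),
         n_excluded = nrow(filt$excluded),
         n_retained = nrow(filt$retained),
         n_imputed_cells = n_imputed,
         total_cells = nrow(complete) * (ncol(complete) - 1L),
         n_train = nrow(tr), n_test = nrow(te)))
}
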