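make_pred_tbl <- function(X) {
  dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%03d", seq_len(nrow(X)))),
    tibble::as_tibble(X))
}

test_that("missingness filter excludes at the 4-missing boundary", {
  X <- matrix(rnorm(5 * 10), 5, dimnames = list(NULL, paste0("v", 1:10)))
  X[1, 1:4] <- NA  # exactly 4 missing -> excluded
  X[2, 1:3] <- NA  # 3 missing -> retained
  tbl <- make_pred_tbl(X)
  res <- filter_by_missingness(tbl, max_missing = 3)
  expect_identical(res$report$status,
                   c("excluded", rep("retained", 4)))
  expect_identical(nrow(res$retained) + nrow(res$excluded), nrow(tbl))

  # all rows at the boundary: none excluded, all flagged for imputation
  X2 <- matrix(rnorm(4 * 10), 4, dimnames = list(NULL, paste0("v", 1:10)))
  X2[cbind(rep(1:4, each = 3), c(1:3, 2:4, 3:5, 4:6))] <- NA
  res2 <- filter_by_missingness(make_pred_tbl(X2))
  expect_identical(nrow(res2$excluded), 0L)
  expect_true(all(res2$report$n_missing == 3L))
})

test_that("PMM imputation is identity without missingness and stays in", {
  X <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("v", 1:4)))
  tbl <- make_pred_tbl(X)
  expect_identical(impute_pmm(tbl, seed = 1), tbl)

  # binary column: imputations must come from the observed support {0, 1}
  withr::with_seed(2, {
    Xb <- cbind(v1 = rnorm(60), v2 = rnorm(60),
                b = rbinom(60, 1, 0.4) * 1.0)
    Xb[sample(60, 8), "b"] <- NA
  })
  out <- impute_pmm(make_pred_tbl(Xb), seed = 3)
  expect_true(all(out$b %in% c(0, 1)))

  # observed cells untouched
  obs <- !is.na(Xb)
  expect_identical(as.matrix(out[, -1])[obs], Xb[obs])
})

test_that("PMM with one donor matches the collinear column exactly", {
  # v2 = 2 * v1 with no noise: the predicted mean for the missing v2 cell
  # identifies the donor with the same v1, so donors = 1 must return that
  # donor's observed value (verified by brute force over the donor pool)
  v1 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  v2 <- 2 * v1
  v2[3] <- NA
  tbl <- make_pred_tbl(cbind(v1 = v1, v2 = v2))
  out <- impute_pmm(tbl, donors = 1, n_iterations = 2, seed = 1)
  pool_values <- v2[-3]
  pred_target <- 2 * v1[3]
  brute <- pool_values[which.min(abs(pool_values - pred_target))]
  expect_identical(out$v2[3], brute)
})

test_that("train/test split has floor-rule sizes and is seed-deterministic", {
  ids <- sprintf("P%03d", 1:248)
  s1 <- split_train_test(ids, seed = 4)
  expect_identical(sum(s1$split == "train"), 198L)
  expect_identical(sum(s1$split == "test"), 50L)
  expect_identical(s1, split_train_test(ids, seed = 4))
  expect_false(identical(s1$split, split_train_test(ids, seed = 5)$split))

  s2 <- split_train_test(sprintf("P%d", 1:5), seed = 1)
  expect_identical(sum(s2$split == "train"), 4L)
  expect_error(split_train_test(ids, train_fraction = 1.2), "fraction")
})

test_that("standardization anchors to the training split", {
  tr <- make_pred_tbl(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  te <- make_pred_tbl(cbind(a = c(2, 2), b = c(30, 30)))
  std <- standardize_predictors(tr, te)
  expect_equal(std$train$a, c(-1, 0, 1))              # sample SD = 1
  expect_equal(mean(std$train$b), 0, tolerance = 1e-10)
  expect_equal(sd(std$train$b), 1, tolerance = 1e-10)
  expect_equal(std$test$a, c(0, 0))  # test value at train mean -> z = 0
  expect_true(all(is.finite(std$test$b)))  # constant test col is fine

  const <- make_pred_tbl(cbind(a = c(1, 1, 1), b = 1:3))
  expect_error(standardize_predictors(const), "zero-variance")
  dropped <- standardize_predictors(const, on_zero_variance = "drop")
  expect_identical(names(dropped$train), c("participant_id", "b"))
})

test_that("full preprocessing chain reduces to split+standardize when complete", {
  co <- generate_cohort(cohort_config(n_participants = 60,
                                      missing_rate = 0, seed = 2))
  prep <- preprocess_cohort(co, seed = 9)
  expect_identical(prep$report$n_excluded, 0L)
  expect_identical(prep$report$n_imputed_cells, 0L)
  mu <- colMeans(as.matrix(prep$train[, -1]))
  expect_true(all(abs(mu) < 1e-10))
  expect_identical(prep$report$n_train, 48L)
  expect_identical(prep$report$n_test, 12L)
})

test_that("imputed-cell fraction tracks the injected MCAR rate", {
  co <- generate_cohort(cohort_config(n_participants = 248,
                                      missing_rate = 0, seed = 3))
  co <- inject_missingness(co, rate = 0.02, seed = 5)
  n_miss <- sum(is.na(as.matrix(co$predictors[, -1])))
  expected <- 0.02 * 248 * 65
  expect_lt(abs(n_miss - expected), 4 * sqrt(expected * 0.98))
  expect_identical(co$missing_info$n_masked, as.integer(n_miss))
})
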