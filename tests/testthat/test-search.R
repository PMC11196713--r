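# Planted-signal training data for the subset searches: two strong
# marginal predictors among noise, split 80/20.
make_search_data <- function(n = 240, p = 10, seed = 21) {
  withr::with_seed(seed, {
    y <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.36, 0.39))
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- sprintf("P%02d", seq_len(p))
    X[, 1] <- X[, 1] + c(1.1, 1.1, -1.3)[y]   # clusters {1,2} vs 3
    X[, 2] <- X[, 2] + c(1.5, -0.6, -0.6)[y]  # cluster 1 vs {2,3}
    tr <- sample(n, floor(0.8 * n))
    list(Xtr = scale(X[tr, ]), ytr = y[tr],
         Xte = scale(X[-tr, ]), yte = y[-tr])
  })
}

test_that("binomial coefficients are exact at the search's sizes", {
  expect_identical(count_combinations(49, 5), 1906884)
  expect_identical(count_combinations(65, 10), 179013799328)
  expect_identical(count_combinations(65, 0), 1)
  expect_identical(count_combinations(65, 4), 677040)
  # multiplicative formula against R's own choose() across a sweep
  for (n in c(0:8, 20, 65)) {
    for (k in 0:min(n, 10)) {
      expect_identical(count_combinations(n, k), round(choose(n, k)))
    }
  }
  expect_error(count_combinations(3, 4), "exceed")
})

test_that("plan_level reproduces the budgeted eliminations", {
  expect_identical(plan_level(65, 5, 2e6), 16L)
  expect_identical(plan_level(65, 4, 2e6), 0L)
  expect_identical(plan_level(10, 3, 1000), 0L)
  expect_error(plan_level(10, 3, 0), "budget")

  # oracle: linear scan over m, plus the sandwich property
  withr::with_seed(1, {
    for (rep in 1:25) {
      pool <- sample(8:60, 1)
      k <- sample(2:min(8, pool), 1)
      budget <- sample(50:5000, 1)
      m <- plan_level(pool, k, budget)
      scan <- 0L
      while (choose(pool - scan, k) > budget) scan <- scan + 1L
      expect_identical(m, scan)
      expect_lte(count_combinations(pool - m, k), budget)
      if (m > 0) expect_gt(count_combinations(pool - m + 1, k), budget)
    }
  })
})

test_that("backward elimination recovers planted signal and counts models", {
  d <- make_search_data(p = 10)
  trace <- backward_eliminate(d$Xtr, d$ytr, d$Xte, d$yte,
                              budget = search_budget(200, 4))
  # exhaustive enumeration: binomial counts at every level
  for (lv in trace$levels) {
    expect_identical(lv$n_models_evaluated,
                     as.integer(count_combinations(length(lv$pool),
                                                   lv$level)))
  }
  # level-1 best model equals a direct scan over all singletons
  accs <- vapply(seq_len(ncol(d$Xtr)), function(j) {
    res <- funcpheno:::cpp_lda_subset_search(
      d$Xtr, as.integer(factor(d$ytr)), d$Xte,
      as.integer(factor(d$yte)), matrix(j - 1L, 1, 1), 3L)
    res[1, 2]
  }, 0)
  best1 <- trace$levels[[1]]$best_models$predictors[[1]]
  expect_identical(best1, colnames(d$Xtr)[which.max(accs)])
  # the two signal predictors persist in every best model from level 2 on
  for (lv in trace$levels[-1]) {
    expect_true(all(c("P01", "P02") %in% lv$best_models$predictors[[1]]))
  }
})

test_that("no eliminations happen when the budget covers the full pool", {
  d <- make_search_data(p = 6, seed = 5)
  trace <- backward_eliminate(d$Xtr, d$ytr, d$Xte, d$yte,
                              budget = search_budget(1e4, 3))
  expect_true(all(vapply(trace$levels, function(lv) {
    length(lv$eliminated_here) == 0L
  }, TRUE)))
  # with an unconstrained budget and max_level = p, the last level holds
  # the full predictor set as its single candidate
  trace_full <- backward_eliminate(d$Xtr, d$ytr, d$Xte, d$yte,
                                   budget = search_budget(1e6, 6))
  last <- trace_full$levels[[6]]
  expect_identical(last$n_models_evaluated, 1L)
  expect_identical(last$best_models$predictors[[1]],
                   sort(colnames(d$Xtr)))
})

test_that("forward selection fixes planted marginal predictors early", {
  d <- make_search_data(p = 10, seed = 31)
  trace <- forward_select(d$Xtr, d$ytr, d$Xte, d$yte,
                          budget = search_budget(1e4, 4),
                          combo_sizes = 1:4)
  expect_true(all(c("P01", "P02") %in% trace$fixed_predictors$predictor))
  first_iter <- trace$fixed_predictors$iteration_fixed[
    match(c("P01", "P02"), trace$fixed_predictors$predictor)]
  expect_true(all(first_iter == 1L))
  expect_true(trace$terminated_reason %in% c("natural", "pool_exhausted"))
  # fixed set grows monotonically by construction of iteration_fixed
  expect_true(!is.unsorted(trace$fixed_predictors$iteration_fixed))
})

test_that("pure-noise forward search terminates", {
  d <- withr::with_seed(99, {
    n <- 150
    y <- sample(1:3, n, replace = TRUE)
    X <- matrix(rnorm(n * 8), n)
    colnames(X) <- sprintf("N%02d", 1:8)
    tr <- sample(n, 120)
    list(Xtr = scale(X[tr, ]), ytr = y[tr],
         Xte = scale(X[-tr, ]), yte = y[-tr])
  })
  trace <- forward_select(d$Xtr, d$ytr, d$Xte, d$yte,
                          budget = search_budget(1e4, 4),
                          combo_sizes = 1:4, max_iterations = 5)
  expect_true(trace$terminated_reason != "max_iterations")
})

test_that("forward iteration arithmetic matches the binomial sums", {
  expect_identical(
    sum(vapply(1:4, function(s) count_combinations(65, s), 0)),
    65 + 2080 + 43680 + 677040)
  expect_identical(65 + 2080 + 43680 + 677040, 722865)
})

test_that("best-model report round-trips through serialization", {
  d <- make_search_data(p = 6, seed = 8)
  trace <- backward_eliminate(d$Xtr, d$ytr, d$Xte, d$yte,
                              budget = search_budget(100, 2))
  rep1 <- best_models_report(trace)
  expect_identical(nrow(rep1), 2L)
  json <- jsonlite::toJSON(rep1, digits = NA)
  rep2 <- tibble::as_tibble(jsonlite::fromJSON(json))
  expect_equal(as.data.frame(rep2), as.data.frame(rep1))
})
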