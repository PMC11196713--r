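# Binary-outcome fixture with one strongly predictive column among noise.
make_lasso_data <- function(n = 300, p = 21, seed = 14) {
  withr::with_seed(seed, {
    y <- sample(1:3, n, replace = TRUE)
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- sprintf("V%02d", seq_len(p))
    X[, 1] <- X[, 1] + 2.5 * (y == 3)  # near-perfect marker of cluster 3
    tr <- sample(n, 240)
    list(Xtr = X[tr, ], ytr = y[tr], Xte = X[-tr, ], yte = y[-tr])
  })
}

test_that("one-vs-rest lasso finds the planted marker", {
  d <- make_lasso_data()
  fit <- fit_ovr_lasso(d$Xtr, d$ytr, d$Xte, d$yte, target_cluster = 3,
                       seed = 2)
  expect_true("V01" %in% fit$selected_predictors)
  expect_gte(fit$test_accuracy, 0.85)
  expect_gt(fit$lambda_selected, 0)
  expect_identical(fit$chance_level, 0.5)
  # refit keeps every selected predictor with a nonzero coefficient
  refit <- fit$refit_coefficients
  kept <- refit$coefficient[refit$predictor %in% fit$selected_predictors]
  expect_true(all(kept != 0))
})

test_that("ridge refit matches a penalized IRLS oracle and shares duplicates", {
  withr::with_seed(3, {
    n <- 200
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(n, 1, plogis(1.2 * X[, 1] - 0.8 * X[, 2]))
  })
  refit <- ridge_refit(X, y, c("a", "b", "c"), seed = 4)
  lam <- attr(refit, "lambda")
  # independent IRLS for the glmnet objective:
  # -(1/n) loglik + lambda/2 * ||beta||^2, intercept unpenalized
  beta <- rep(0, 4)
  Xd <- cbind(1, X)
  for (it in 1:200) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    P <- diag(c(0, rep(lam, 3))) * n
    beta_new <- solve(t(Xd) %*% (w * Xd) + P, t(Xd) %*% (w * z))
    if (max(abs(beta_new - beta)) < 1e-12) break
    beta <- drop(beta_new)
  }
  expect_equal(refit$coefficient, unname(beta), tolerance = 1e-4)

  # duplicated predictor columns share the coefficient roughly in half
  X2 <- cbind(X[, "a", drop = FALSE], a2 = X[, "a"])
  single <- ridge_refit(X[, "a", drop = FALSE], y, "a", seed = 5)
  dup <- ridge_refit(X2, y, c("a", "a2"), seed = 5)
  ca <- dup$coefficient[dup$predictor == "a"]
  ca2 <- dup$coefficient[dup$predictor == "a2"]
  expect_equal(ca, ca2, tolerance = 0.02)  # numeric path tolerance
  single_a <- single$coefficient[single$predictor == "a"]
  expect_lt(ca, 0.8 * single_a)  # penalty shared across the duplicates
  expect_error(ridge_refit(X, y, character(0)), "empty")

  # sign sanity: a +2 SD shifted predictor gets a positive coefficient
  withr::with_seed(6, {
    yb <- rep(0:1, each = 50)
    xb <- matrix(rnorm(100) + 2 * yb, dimnames = list(NULL, "s"))
  })
  rs <- ridge_refit(xb, yb, "s", seed = 7)
  expect_gt(rs$coefficient[rs$predictor == "s"], 0)
})

test_that("holm adjustment matches the step-down definition", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "holm"),
               c(0.03, 0.04, 0.04))
  withr::with_seed(8, {
    for (i in 1:20) {
      m <- sample(2:8, 1)
      p <- runif(m)
      # step-down by definition with monotonicity enforcement
      o <- order(p)
      adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
      expect_equal(p.adjust(p, "holm")[o], adj)
      expect_true(all(p.adjust(p, "holm") <= pmin(1, m * p) + 1e-12))
    }
  })
})

test_that("fisher's exact p equals hypergeometric tail enumeration on 2x2", {
  tab <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  ft <- fisher.test(tab)
  # enumerate all tables with the observed margins; two-sided p sums the
  # probabilities of tables no more likely than the observed one
  r1 <- 10; c1 <- 9; n <- 20
  probs <- vapply(max(0, c1 - (n - r1)):min(r1, c1), function(a) {
    dhyper(a, r1, n - r1, c1)
  }, 0)
  obs <- dhyper(8, r1, n - r1, c1)
  p_brute <- sum(probs[probs <= obs * (1 + 1e-7)])
  expect_equal(ft$p.value, p_brute, tolerance = 1e-10)
  # and compare_groups reports the same number for the same data
  clusters <- rep(1:2, each = 10)
  values <- c(rep("a", 8), rep("b", 2), rep("a", 1), rep("b", 9))
  cg <- compare_groups(values, clusters, kind = "categorical")
  expect_equal(cg$p_value, ft$p.value, tolerance = 1e-10)
  expect_identical(cg$method, "fisher_exact")
})

test_that("group comparisons star the planted dissociation pattern", {
  withr::with_seed(9, {
    cl <- sample(1:3, 400, replace = TRUE)
    avol <- rnorm(400) + c(0.8, 0.8, -1.0)[cl]
    anhe <- rnorm(400) + c(1.2, -0.4, -0.4)[cl]
    null <- rnorm(400)
  })
  ca <- compare_groups(avol, cl)
  sig <- function(tbl, cmp) {
    tbl$p_adjusted[tbl$comparison == cmp] < 0.05
  }
  expect_false(sig(ca, "1 vs 2"))
  expect_true(sig(ca, "1 vs 3"))
  expect_true(sig(ca, "2 vs 3"))
  cb <- compare_groups(anhe, cl)
  expect_true(sig(cb, "1 vs 2"))
  expect_true(sig(cb, "1 vs 3"))
  expect_false(sig(cb, "2 vs 3"))
  cn <- compare_groups(null, cl)
  expect_true(all(cn$method[1:3] == "welch_t"))
  expect_identical(nrow(cn), 4L)  # 3 pairwise + overall anova
  expect_true(all(c("welch_t", "anova") %in% cn$method))
})

test_that("consensus intersects the two searches and fits a final model", {
  d <- withr::with_seed(15, {
    n <- 220
    y <- sample(1:3, n, replace = TRUE)
    X <- matrix(rnorm(n * 8), n)
    colnames(X) <- sprintf("P%02d", 1:8)
    X[, 1] <- X[, 1] + c(1.1, 1.1, -1.3)[y]
    X[, 2] <- X[, 2] + c(1.5, -0.6, -0.6)[y]
    tr <- sample(n, 176)
    list(Xtr = scale(X[tr, ]), ytr = y[tr],
         Xte = scale(X[-tr, ]), yte = y[-tr],
         X = scale(X), y = y)
  })
  bt <- backward_eliminate(d$Xtr, d$ytr, d$Xte, d$yte,
                           budget = search_budget(300, 3))
  ft <- forward_select(d$Xtr, d$ytr, d$Xte, d$yte,
                       budget = search_budget(1e4, 4), combo_sizes = 1:4)
  lf <- list(fit_ovr_lasso(d$Xtr, d$ytr, d$Xte, d$yte, 3, seed = 1),
             fit_ovr_lasso(d$Xtr, d$ytr, d$Xte, d$yte, 2, seed = 1))
  cons <- build_consensus(bt, ft, lf, d$X, d$y)
  expect_true(all(cons$key_correlates %in%
                    intersect(cons$backward_set, cons$forward_set)))
  expect_true(all(c("P01", "P02") %in% cons$key_correlates))
  expect_s3_class(cons$final_model, "fp_lda")
  # definition check: balanced accuracy is the mean of per-class recalls
  m <- cons$final_metrics
  expect_equal(m$balanced_accuracy, mean(m$per_class_recall))

  # lasso sets are reported for corroboration
  expect_identical(names(cons$lasso_sets),
                   c("cluster3_vs_rest", "cluster2_vs_rest"))
})
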