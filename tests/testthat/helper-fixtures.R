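# Shared fixtures, built in code at test time.

# Two well-separated Gaussian blobs in `d` dimensions.
make_blobs <- function(n_per = 20, d = 2, sep = 10, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), n_per),
               matrix(rnorm(n_per * d, mean = sep), n_per))
    colnames(x) <- paste0("item", seq_len(d))
    list(x = x, truth = rep(1:2, each = n_per))
  })
}

# Three separated blobs for multi-class checks.
make_blobs3 <- function(n_per = 30, d = 3, sep = 8, seed = 42) {
  withr::with_seed(seed, {
    centers <- rbind(c(0, 0, 0), c(sep, 0, 0), c(0, sep, 0))[, seq_len(d),
                                                             drop = FALSE]
    x <- do.call(rbind, lapply(1:3, function(g) {
      matrix(rnorm(n_per * d), n_per) +
        matrix(centers[g, ], n_per, d, byrow = TRUE)
    }))
    colnames(x) <- paste0("item", seq_len(d))
    list(x = x, truth = rep(1:3, each = n_per))
  })
}

# Small labelled dataset with class-dependent means for LDA checks.
make_lda_toy <- function(n_per = 4, p = 2, sep = 2, seed = 7) {
  withr::with_seed(seed, {
    centers <- cbind(rbind(c(0, 0), c(sep, 0), c(0, sep)),
                     matrix(0, 3, max(0, p - 2)))[, seq_len(p),
                                                  drop = FALSE]
    X <- do.call(rbind, lapply(1:3, function(g) {
      matrix(rnorm(n_per * p, sd = 1), n_per) +
        matrix(centers[g, ], n_per, p, byrow = TRUE)
    }))
    colnames(X) <- paste0("v", seq_len(p))
    list(X = X, y = rep(1:3, each = n_per))
  })
}

# Independent oracle: equal-covariance Gaussian classification rule,
# written naively (explicit pooled covariance, explicit discriminant
# scores), sharing no code with the package's fit path.
oracle_lda_predict <- function(Xtr, ytr, Xnew, priors = NULL) {
  ytr <- factor(ytr)
  K <- nlevels(ytr)
  n <- nrow(Xtr)
  means <- lapply(levels(ytr), function(g) {
    colMeans(Xtr[ytr == g, , drop = FALSE])
  })
  S <- Reduce(`+`, lapply(levels(ytr), function(g) {
    Xi <- Xtr[ytr == g, , drop = FALSE]
    crossprod(sweep(Xi, 2, colMeans(Xi)))
  }))
  Sigma <- S / (n - K)
  if (is.null(priors)) priors <- as.vector(table(ytr)) / n
  A <- solve(Sigma)
  apply(Xnew, 1, function(x) {
    scores <- vapply(seq_len(K), function(g) {
      m <- means[[g]]
      drop(x %*% A %*% m - 0.5 * m %*% A %*% m) + log(priors[g])
    }, 0)
    levels(ytr)[which.max(scores)]
  })
}

# Naive LOOCV by explicit refits, used as the oracle for the fast path.
oracle_loocv <- function(X, y) {
  n <- nrow(X)
  correct <- vapply(seq_len(n), function(i) {
    pred <- oracle_lda_predict(X[-i, , drop = FALSE], y[-i],
                               X[i, , drop = FALSE])
    pred == as.character(y[i])
  }, TRUE)
  mean(correct)
}

# Predictor tibble for small custom cohorts.
toy_predictor_table <- function(p, prefix = "X") {
  tibble::tibble(name = sprintf("%s%02d", prefix, seq_len(p)),
                 block = "CUSTOM", kind = "continuous",
                 bilateral_pair = NA_character_)
}
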