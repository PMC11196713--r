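test_that("two correlated items give the closed-form eigenvalues 1 +/- r", {
  r <- 0.8
  x <- withr::with_seed(1, {
    z <- rnorm(4000)
    cbind(a = z, b = r * z + sqrt(1 - r^2) * rnorm(4000))
  })
  # use the exact sample correlation for the closed form
  rs <- cor(x)[1, 2]
  sol <- pca_components(x, n_components = 1)
  expect_equal(sol$eigenvalues, c(1 + rs, 1 - rs), tolerance = 1e-10)
  expect_equal(sum(sol$eigenvalues), 2, tolerance = 1e-8)
})

test_that("Kaiser's rule refuses independent items and flags constants", {
  # exactly orthogonal items: correlation is the identity, all eigenvalues
  # are exactly 1, so Kaiser's strict rule retains nothing
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_error(pca_components(x), "Kaiser")
  sol <- pca_components(x, n_components = 2)
  expect_equal(sol$eigenvalues, c(1, 1))
  xc <- cbind(x, const = rep(1, 4))
  expect_error(pca_components(xc), "zero variance")
})

test_that("eigenvalue sum equals the number of items (trace conservation)", {
  co <- generate_cohort(cohort_config(n_participants = 120,
                                      missing_rate = 0, seed = 5))
  sol <- pca_components(co$functioning)
  expect_equal(sum(sol$eigenvalues), 11, tolerance = 1e-8)
  expect_true(all(diff(sol$eigenvalues) <= 1e-12))  # descending
  expect_true(all(sol$eigenvalues > -1e-12))
})

test_that("promax leaves perfect simple structure unchanged", {
  L <- rbind(c(0.8, 0), c(0.7, 0), c(0.75, 0),
             c(0, 0.8), c(0, 0.7), c(0, 0.75))
  rownames(L) <- paste0("it", 1:6)
  colnames(L) <- c("F1", "F2")
  rot <- promax_rotate(L)
  # pattern recovered up to column permutation/sign (signs normalized)
  recovered <- abs(rot$pattern)
  expect_equal(unname(recovered[recovered > 0.1]),
               unname(abs(L[abs(L) > 0.1])), tolerance = 0.05)
  expect_equal(max(abs(recovered[abs(L) < 0.1])), 0, tolerance = 0.05)
  phi <- rot$factor_correlations
  expect_equal(diag(phi), c(1, 1), tolerance = 1e-8)
  expect_equal(phi, t(phi))
  expect_lt(abs(phi[1, 2]), 0.1)
})

test_that("promax recovers a planted oblique loading structure from data", {
  # items loading 0.85 on one factor, 0.05 elsewhere; factors correlated
  withr::with_seed(11, {
    n <- 600
    Phi <- matrix(0.4, 3, 3); diag(Phi) <- 1
    F <- matrix(rnorm(n * 3), n) %*% chol(Phi)
    L <- matrix(0.05, 9, 3)
    for (j in 1:3) L[(3 * j - 2):(3 * j), j] <- 0.85
    X <- F %*% t(L) + matrix(rnorm(n * 9, sd = 0.4), n)
    colnames(X) <- paste0("it", 1:9)
  })
  sol <- pca_components(X)
  expect_identical(sol$n_components, 3L)
  got <- apply(abs(sol$pattern), 1, which.max)
  planted <- rep(1:3, each = 3)
  # one recovered component per planted factor, consistently assigned
  expect_identical(length(unique(got[1:3])), 1L)
  expect_identical(length(unique(got[4:6])), 1L)
  expect_identical(length(unique(got[7:9])), 1L)
  expect_identical(sort(unique(got)), 1:3)
})

test_that("power = 1 stays close to the varimax pre-rotation", {
  withr::with_seed(4, {
    L <- matrix(rnorm(12), 6, 2)
  })
  v <- varimax(L)
  rot <- promax_rotate(L, power = 1)
  # compare absolute column-matched loadings
  vload <- unclass(v$loadings)
  match_cols <- apply(abs(cor(rot$pattern, vload)), 1, which.max)
  for (j in seq_len(2)) {
    expect_equal(abs(rot$pattern[, j]), abs(vload[, match_cols[j]]),
                 tolerance = 0.05)
  }
})

test_that("loading masks blank below 0.3 and flag the primary loading", {
  P <- rbind(item1 = c(0.91, 0.29), item2 = c(0.25, 0.45),
             item3 = c(0.1, 0.2))
  colnames(P) <- c("PC1", "PC2")
  m <- mask_loadings(P)
  expect_identical(m$PC1[1], "*0.91*")
  expect_identical(m$PC2[1], "")        # 0.29 masked at the boundary
  expect_identical(m$PC2[2], "*0.45*")
  expect_identical(unname(unlist(m[3, c("PC1", "PC2")])), c("", ""))
  expect_identical(m$primary, c("PC1", "PC2", "PC2"))
})

test_that("component scores are centered, unit variance, and well oriented", {
  co <- generate_cohort(cohort_config(n_participants = 300,
                                      missing_rate = 0, seed = 6))
  sol <- pca_components(co$functioning)
  sc <- as.matrix(sol$scores[, -1])
  expect_true(all(abs(colMeans(sc)) < 1e-10))  # item means -> score 0
  expect_equal(unname(apply(sc, 2, var)), rep(1, ncol(sc)),
               tolerance = 1e-6)
  # cluster 3 participants sit highest on every component
  cl <- co$participants$true_cluster
  for (j in seq_len(ncol(sc))) {
    mns <- tapply(sc[, j], cl, mean)
    expect_identical(which.max(mns), c("3" = 3L))
  }
  # rotation preserves communalities of the retained space
  S <- sol$pattern %*% sol$factor_correlations
  h_rot <- rowSums(sol$pattern * S)
  h_un <- rowSums(sol$loadings^2)
  expect_equal(unname(h_rot), unname(h_un), tolerance = 1e-6)
  expect_error(component_scores(co$functioning[, 1:6], sol), "match")
})
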