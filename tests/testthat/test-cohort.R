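test_that("cluster shares follow the configured prevalences", {
  co <- generate_cohort(cohort_config(seed = 1, missing_rate = 0))
  n <- nrow(co$participants)
  expect_identical(n, 282L)
  shares <- tabulate(co$participants$true_cluster, 3) / n
  target <- c(0.25, 0.36, 0.39)
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(shares - target) < 4 * se))
})

test_that("the generator is bit-identical under one seed and config", {
  cfg <- cohort_config(n_participants = 50, seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_participants = 50, seed = 78)
  expect_false(identical(generate_cohort(cfg)$functioning,
                         generate_cohort(cfg2)$functioning))
})

test_that("no latent noise and identical profiles collapse functioning", {
  prof <- matrix(0.5, 3, 3,
                 dimnames = list(NULL, c("independent", "social", "role")))
  cfg <- cohort_config(n_participants = 20, component_profiles = prof,
                       component_noise = 1e-12, item_noise_sd = 0,
                       missing_rate = 0, seed = 3)
  co <- generate_cohort(cfg)
  f <- as.matrix(co$functioning[, -1])
  expect_lt(max(apply(f, 2, sd)), 1e-6)
})

test_that("bilateral volume pairs carry the configured correlation", {
  # no effects on the pair so the raw noise correlation is observable
  cfg <- cohort_config(n_participants = 10000,
                       predictor_effects = list(),
                       interaction_effects = list(),
                       bilateral_r = 0.84, missing_rate = 0, seed = 9)
  co <- generate_cohort(cfg)
  r <- cor(co$predictors[["Left Hippocampal Volume"]],
           co$predictors[["Right Hippocampal Volume"]])
  expect_lt(abs(r - 0.84), 0.02)
})

test_that("planted predictor effects are recovered at scale", {
  tbl <- toy_predictor_table(3)
  cfg <- cohort_config(
    n_participants = 5000, predictors = tbl,
    predictor_effects = list(X01 = c(1, 1, -1)),
    interaction_effects = list(), missing_rate = 0, seed = 10)
  co <- generate_cohort(cfg)
  m <- tapply(co$predictors$X01, co$participants$true_cluster, mean)
  expect_true(all(abs(m - c(1, 1, -1)) < 0.05))
  # nuisance predictor stays centered
  m2 <- tapply(co$predictors$X03, co$participants$true_cluster, mean)
  expect_true(all(abs(m2) < 0.1))
})

test_that("interaction-only predictors separate within partner tertiles", {
  tbl <- toy_predictor_table(2)
  cfg <- cohort_config(
    n_participants = 6000, predictors = tbl,
    predictor_effects = list(X01 = c(1, 0, -1)),
    interaction_effects = list(
      X02 = list(partner = "X01", means = c(-1, 0, 1))),
    missing_rate = 0, seed = 12)
  co <- generate_cohort(cfg)
  x2 <- co$predictors$X02
  cl <- co$participants$true_cluster
  part <- co$predictors$X01
  top <- part > quantile(part, 2 / 3)
  # conditional on the top tertile: planted separation visible
  cond <- tapply(x2[top], cl[top], mean)
  expect_gt(cond[["3"]] - cond[["1"]], 1)
  # marginally: attenuated well below the conditional separation
  marg <- tapply(x2, cl, mean)
  expect_lt(abs(marg[["3"]] - marg[["1"]]),
            (cond[["3"]] - cond[["1"]]) / 2)
})

test_that("unknown effect names and invalid configs error", {
  expect_error(cohort_config(predictor_effects = list(Bogus = c(1, 0, 0))),
               "unknown predictor")
  expect_error(cohort_config(n_participants = 0), "positive")
  expect_error(cohort_config(prevalences = c(0.3, 0.3, 0.3)), "summing|sum")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(bilateral_r = 1.5), "bilateral_r")
})

test_that("missingness injection is MCAR on predictors only", {
  cfg <- cohort_config(n_participants = 40, missing_rate = 0, seed = 2)
  co <- generate_cohort(cfg)
  co0 <- inject_missingness(co, rate = 0, seed = 1)
  expect_false(any(cohort_missing_mask(co0)))
  co5 <- inject_missingness(co, rate = 0.4, seed = 1)
  expect_false(anyNA(as.matrix(co5$functioning[, -1])))
  expect_error(inject_missingness(co, rate = 1.2), "rate")
})

test_that("every 2x2 mask pattern is attainable across seeds", {
  tbl <- toy_predictor_table(2)
  cfg <- cohort_config(n_participants = 2, predictors = tbl,
                       predictor_effects = list(),
                       interaction_effects = list(),
                       missing_rate = 0, seed = 5)
  co <- generate_cohort(cfg)
  seen <- character(0)
  for (s in 1:300) {
    m <- cohort_missing_mask(inject_missingness(co, 0.5, seed = s))
    seen <- union(seen, paste(as.integer(m), collapse = ""))
  }
  expect_identical(length(seen), 16L)
})

test_that("cohorts round-trip through the CSV dialect", {
  co <- generate_cohort(cohort_config(n_participants = 30,
                                      missing_rate = 0.05, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$participants$true_cluster,
                   co$participants$true_cluster)
  expect_equal(as.matrix(back$functioning[, -1]),
               as.matrix(co$functioning[, -1]), tolerance = 1e-9)
  expect_equal(as.matrix(back$predictors[, -1]),
               as.matrix(co$predictors[, -1]), tolerance = 1e-9)
  expect_identical(cohort_missing_mask(back), cohort_missing_mask(co))

  # malformed inputs
  writeLines(c("participant_id,a", "P1,1", "P1,2"),
             file.path(dir, "participants.csv"))
  expect_error(read_cohort(dir), "duplicate")
  writeLines(c("participant_id,true_cluster", "P1,1", "P2,oops"),
             file.path(dir, "participants.csv"))
  expect_error(read_cohort(dir), "non-numeric")
})

test_that("empty predictor cells read back as missing, not zero", {
  dir <- withr::local_tempdir()
  writeLines(c("participant_id,true_cluster", "P1,1", "P2,2"),
             file.path(dir, "participants.csv"))
  writeLines(c("participant_id,it1", "P1,0.5", "P2,1.5"),
             file.path(dir, "functioning.csv"))
  writeLines(c("participant_id,v1,v2", "P1,,3", "P2,0,"),
             file.path(dir, "predictors.csv"))
  co <- read_cohort(dir)
  expect_true(is.na(co$predictors$v1[1]))
  expect_identical(co$predictors$v1[2], 0)
  expect_true(is.na(co$predictors$v2[2]))
})
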