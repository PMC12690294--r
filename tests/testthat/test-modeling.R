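test_that("residualization tracks raw TPI when covariate effects are null", {
  cfg <- cohort_config(n_subjects = 60, n_regions = 40,
                       n_nonspecific_regions = 12,
                       covariate_effects = list(age = 0, sex_M = 0,
                                                education = 0,
                                                race = c(Black = 0, Asian = 0,
                                                         Multiple = 0),
                                                study_ADNI = 0, interval = 0),
                       seed = 55L)
  cohort <- generate_cohort(cfg, seed = 55L, longitudinal = FALSE)
  models <- fit_region_mixtures(cohort$suvr, n_restarts = 1)
  tpi <- build_tpi_table(cohort$suvr, models)
  adj <- residualize_tpi(tpi, cohort$metadata)
  expect_gt(stats::cor(as.vector(adj), as.vector(tpi)), 0.99)
})

test_that("residualization is invariant to covariate translation and falls back to OLS", {
  st <- small_stages()
  adj1 <- residualize_tpi(st$tpi, st$cohort$metadata)
  md2 <- st$cohort$metadata
  md2$age <- md2$age + 10
  adj2 <- residualize_tpi(st$tpi, md2)
  expect_equal(adj1, adj2, tolerance = 1e-6)

  adj_ols <- residualize_tpi(st$tpi, st$cohort$metadata, method = "ols")
  expect_identical(dim(adj_ols), dim(st$tpi))

  md3 <- st$cohort$metadata
  md3$age[2] <- NA
  expect_error(residualize_tpi(st$tpi, md3), "age")
  expect_error(residualize_tpi(st$tpi, md3[, -2]), "lacks covariate")
})

test_that("stratified folds partition the cohort and balance amyloid status", {
  md <- medium_cohort()$metadata
  folds <- stratified_kfold(md, k = 5, seed = 17)
  expect_setequal(names(folds), md$subject_id)
  expect_true(all(folds %in% 1:5))
  for (s in c(TRUE, FALSE)) {
    counts <- table(folds[md$subject_id[md$abeta_positive == s]])
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_identical(folds, stratified_kfold(md, k = 5, seed = 17))
  expect_false(identical(folds, stratified_kfold(md, k = 5, seed = 18)))
  expect_error(stratified_kfold(md, k = 1), "at least 2")
})

test_that("rank alignment sorts by raw TPI and applies one permutation throughout", {
  tpi_raw <- matrix(c(0.2, 0.9, -0.5), 1, 3,
                    dimnames = list("s1", c("r1", "r2", "r3")))
  prof <- list("IE-IC" = matrix(c(10, 20, 30), 1, 3,
                                dimnames = dimnames(tpi_raw)))
  out <- rank_align_and_average(tpi_raw, tpi_raw, prof, "s1")
  expect_equal(unname(out$tpi), c(0.9, 0.2, -0.5))
  expect_equal(unname(out$dist[["IE-IC"]]), c(20, 10, 30))
  expect_identical(out$permutations["s1", ], c(2L, 1L, 3L))

  # mirrored rank-aligned distance vectors average to a constant
  tpi2 <- matrix(c(3, 2, 1, 1, 2, 3), 2, 3, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("r1", "r2", "r3")))
  v <- c(5, 7, 9)
  prof2 <- list("IE-IC" = matrix(c(v, v), 2, 3, byrow = TRUE,
                                 dimnames = dimnames(tpi2)))
  out2 <- rank_align_and_average(tpi2, tpi2, prof2, c("a", "b"))
  expect_equal(unname(out2$dist[["IE-IC"]]), rep(mean(v), 3))

  # subjects lacking a profile are excluded with a warning
  prof3 <- prof2
  prof3[["IE-IC"]]["b", 1] <- NA
  expect_warning(out3 <- rank_align_and_average(tpi2, tpi2, prof3, c("a", "b")),
                 "excluding")
  expect_identical(out3$n_subjects, 1L)
})

test_that("group regressions report exact fits and textbook degrees of freedom", {
  d <- seq(0.5, 3.5, length.out = 64)
  f <- suppressWarnings(fit_group_model(1 - d, d))
  expect_equal(f$beta_std, -1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$rmse, 0, tolerance = 1e-9)
  expect_identical(f$df, 62L)
  expect_error(fit_group_model(stats::rnorm(10), rep(1, 10)), "zero variance")

  # standardized slope is sign-invariant under affine predictor rescaling
  set.seed(61)
  y <- stats::rnorm(64); x <- stats::rnorm(64)
  expect_equal(fit_group_model(y, x)$beta_std,
               fit_group_model(y, 2 * x + 5)$beta_std, tolerance = 1e-12)

  # interaction term appears when a group factor is supplied
  g <- rep(c("p", "n"), each = 32)
  fi <- fit_group_model(y, x, group = g)
  expect_true(is.finite(fi$interaction_t))
  expect_true(fi$interaction_p >= 0 && fi$interaction_p <= 1)
})

test_that("held-out evaluation reduces to resubstitution on the training data", {
  set.seed(62)
  x <- stats::rnorm(50); y <- -0.8 * x + stats::rnorm(50, 0, 0.3)
  tr <- fit_group_model(y, x)
  te <- evaluate_model(tr, y, x)
  expect_equal(te$r2, tr$r2, tolerance = 1e-12)
  expect_gt(te$beta_std, 0)

  flat <- tr
  flat$slope <- 0
  expect_error(evaluate_model(flat, y, x), "constant predictions")
  expect_error(evaluate_model(tr, y, x[-1]), "length")
})

test_that("fold comparisons behave at the null and the degenerate constant case", {
  r2 <- cbind(a = c(0.5, 0.6, 0.55, 0.52, 0.58))
  r2 <- cbind(r2, b = r2[, "a"])
  cmp <- compare_folds(r2)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_identical(cmp$df, 4L)

  r2c <- cbind(a = c(0.5, 0.6, 0.55, 0.52, 0.58))
  r2c <- cbind(r2c, b = r2c[, "a"] - 0.1)
  expect_warning(cmpc <- compare_folds(r2c), "constant")
  expect_identical(cmpc$t, Inf)
  expect_equal(cmpc$p, 0)
  expect_error(compare_folds(r2[1, , drop = FALSE]), "2 folds")
})

test_that("the four-variant estimator returns a complete cross-validated fit", {
  st <- small_stages()
  fit <- suppressWarnings(fit_tau_spread(st$tpi, st$profiles,
                                         st$cohort$metadata, st$eps,
                                         k = 4, seed = 7,
                                         residualize = "ols"))
  expect_s3_class(fit, "tau_spread")
  res <- fit$results
  expect_identical(nrow(res), 3L * 4L * 4L * 2L)  # subsets x folds x variants x roles
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_true(all(res$rmse >= 0))
  expect_true(all(res$df[res$role == "train"] == res$n[res$role == "train"] - 2L))

  # raw-TPI group mean is non-increasing in rank by construction
  gv <- rank_align_and_average(st$tpi, st$tpi, st$profiles, fit$included)
  expect_true(all(diff(gv$tpi) <= 1e-12))

  cf <- coef(fit)
  expect_identical(rownames(cf), c("IE-IC", "IE-GC", "GE-IC", "GE-GC"))
  pred <- predict(fit, distance = c(1, 2), variant = "IE-IC")
  expect_equal(pred, cf["IE-IC", "intercept"] + cf["IE-IC", "slope"] * c(1, 2))

  sm <- summary(fit)
  expect_s3_class(sm, "summary.tau_spread")
  expect_output(print(sm), "beta")
  expect_identical(nrow(fit$interaction), 4L * 4L)
})
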