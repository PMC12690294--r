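test_that("config validation rejects inconsistent parameters", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(subject_noise_sd = -1), "subject_noise_sd")
  expect_error(cohort_config(distance_effect = c(a = 1, b = -0.1, floor = 0)),
               "b")
  expect_error(cohort_config(n_regions = 10, n_nonspecific_regions = 10),
               "n_nonspecific_regions")
  cfg <- cohort_config()
  bad_truth <- cfg$mixture_truth
  bad_truth$mu_p[1] <- bad_truth$mu_n[1] - 0.1
  expect_error(cohort_config(mixture_truth = bad_truth), "mu_p > mu_n")
})

test_that("connectomes are symmetric, bounded, dense, and deterministic", {
  cfg <- cohort_config(n_subjects = 5, seed = 7L)
  conn <- generate_connectomes(cfg, seed = 7L)
  expect_identical(dim(conn$template), c(104L, 104L))
  for (w in c(list(conn$template), conn$subjects)) {
    expect_identical(dim(w), c(104L, 104L))
    expect_true(all(diag(w) == 0))
    expect_equal(w, t(w))
    expect_true(all(w >= 0 & w <= 1))
  }
  offdiag <- conn$template[upper.tri(conn$template)]
  expect_gt(mean(offdiag > 0), 0.9)

  again <- generate_connectomes(cfg, seed = 7L)
  expect_identical(conn, again)
  other <- generate_connectomes(cfg, seed = 8L)
  expect_false(identical(conn$template, other$template))
})

test_that("zero subject noise reproduces the template exactly", {
  cfg <- cohort_config(n_subjects = 3, n_regions = 30,
                       n_nonspecific_regions = 8, subject_noise_sd = 0,
                       seed = 3L)
  conn <- generate_connectomes(cfg)
  for (w in conn$subjects) expect_identical(w, conn$template)
})

test_that("SUVR is positive with the designated unimodal split", {
  cohort <- small_cohort()
  expect_true(all(cohort$suvr > 0))
  expect_identical(sum(cohort$truth$unimodal), 12L)
  expect_identical(dim(cohort$suvr),
                   c(60L, 40L))
  expect_true(all(lengths(cohort$truth$epicenters) >= 1))
})

test_that("pathologic draws are distance-independent when b = 0", {
  cfg <- cohort_config(n_subjects = 120, n_regions = 40,
                       n_nonspecific_regions = 12,
                       distance_effect = c(a = 0, b = 0, floor = 0),
                       severity_range = list(abneg = c(0.5, 0.5),
                                             abpos = c(0.5, 0.5)),
                       seed = 5L)
  cohort <- generate_cohort(cfg, seed = 5L, longitudinal = FALSE)
  patho <- attr(cohort$suvr, "pathologic")
  dbar <- attr(cohort$suvr, "dbar")
  mix <- !cohort$truth$unimodal
  # remove forced epicenter draws; remaining draws are Bernoulli(p) with p
  # constant, so the region-level draw rate must not track distance
  is_ep <- t(vapply(rownames(patho), function(id)
    colnames(patho) %in% cohort$truth$epicenters[[id]],
    logical(ncol(patho))))
  rate <- colSums(patho & !is_ep)[mix] / colSums(!is_ep)[mix]
  d <- colMeans(dbar)[mix]
  expect_gt(stats::cor.test(rate, d)$p.value, 0.01)
})

test_that("a strong distance effect raises pathologic occupancy near epicenters", {
  cohort <- medium_cohort()
  patho <- attr(cohort$suvr, "pathologic")
  dbar <- attr(cohort$suvr, "dbar")
  mix <- !cohort$truth$unimodal
  near <- dbar < stats::quantile(dbar[, mix], 0.2)
  far <- dbar > stats::quantile(dbar[, mix], 0.8)
  x_near <- sum(patho[near & matrix(mix, nrow(dbar), ncol(dbar), byrow = TRUE)])
  n_near <- sum(near[, mix])
  x_far <- sum(patho[far & matrix(mix, nrow(dbar), ncol(dbar), byrow = TRUE)])
  n_far <- sum(far[, mix])
  pt <- stats::prop.test(c(x_near, x_far), c(n_near, n_far),
                         alternative = "greater")
  expect_lt(pt$p.value, 1e-6)
})

test_that("longitudinal change is flat when c1 = 0 and noise-free", {
  cfg <- cohort_config(n_subjects = 30, n_regions = 30,
                       n_nonspecific_regions = 8,
                       longitudinal = list(c0 = 0.01, c1 = 0, noise_sd = 0,
                                           mean_interval = 3, sd_interval = 1,
                                           fraction = 1),
                       seed = 9L)
  cohort <- generate_cohort(cfg, seed = 9L)
  rate <- cohort$longitudinal$rate_truth
  mix <- !cohort$truth$unimodal[colnames(rate)]
  expect_true(all(abs(rate[, mix] - 0.01) < 1e-12))
  expect_true(all(rate[, !mix] == 0))
  expect_true(all(cohort$longitudinal$intervals > 0))
})

test_that("realized TPI-scale change recovers the distance slope -c1", {
  cohort <- memo("slope_cohort",
                 generate_cohort(cohort_config(n_subjects = 120, seed = 11L),
                                 seed = 11L))
  lg <- cohort$config$longitudinal
  mt <- cohort$config$mixture_truth
  mix_idx <- which(!cohort$truth$unimodal)
  ids <- rownames(cohort$longitudinal$followup)
  iv <- cohort$longitudinal$intervals
  dbar <- attr(cohort$suvr, "dbar")[ids, , drop = FALSE]

  true_tpi <- function(x, row)
    stats::pnorm(x, row$mu_p, row$sigma_p) +
      stats::pnorm(x, row$mu_n, row$sigma_n) - 1
  # restrict to regions with headroom below the TPI ceiling, where the
  # imposed linear drift is not attenuated by clipping
  slopes <- vapply(ids, function(id) {
    t0 <- vapply(mix_idx, function(j) true_tpi(cohort$suvr[id, j], mt[j, ]),
                 numeric(1))
    t1 <- vapply(mix_idx, function(j)
      true_tpi(cohort$longitudinal$followup[id, j], mt[j, ]), numeric(1))
    keep <- t0 < 0.8 & t1 < 0.95
    ann <- (t1[keep] - t0[keep]) / iv[[id]]
    unname(stats::coef(stats::lm(ann ~ dbar[id, mix_idx][keep]))[2])
  }, numeric(1))
  est <- mean(slopes)
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(est - (-lg$c1)), 3 * se + 1e-4)
})

test_that("the assembled cohort is complete, balanced, and reproducible", {
  cfg <- cohort_config(n_subjects = 233, seed = 13L)
  cohort <- generate_cohort(cfg, seed = 13L, longitudinal = FALSE)
  expect_identical(nrow(cohort$metadata), 233L)
  expect_identical(sort(names(cohort$connectomes$subjects)),
                   sort(cohort$metadata$subject_id))
  expect_identical(rownames(cohort$suvr), cohort$metadata$subject_id)
  expect_true(sum(cohort$metadata$abeta_positive) %in% 83:85)

  again <- generate_cohort(cfg, seed = 13L, longitudinal = FALSE)
  expect_identical(cohort$suvr, again$suvr)
  expect_identical(cohort$truth$epicenters, again$truth$epicenters)
  other <- generate_cohort(cfg, seed = 14L, longitudinal = FALSE)
  expect_false(identical(cohort$suvr, other$suvr))
})

test_that("cohort artifacts round-trip through plain-text files", {
  cohort <- small_cohort()
  dir <- file.path(tempdir(), "cohort_io")
  write_cohort(cohort, dir)
  id <- cohort$metadata$subject_id[1]
  w <- read_connectome_tsv(file.path(dir, paste0(id, "_connectome.tsv")),
                           expected_labels = cohort$connectomes$labels)
  expect_equal(w, cohort$connectomes$subjects[[id]], tolerance = 1e-12)
  long <- utils::read.csv(file.path(dir, "suvr_baseline.csv"))
  wide <- regional_to_wide(long)
  expect_equal(wide[rownames(cohort$suvr), colnames(cohort$suvr)],
               cohort$suvr, tolerance = 1e-12, ignore_attr = TRUE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_identical(length(gt$epicenters), nrow(cohort$metadata))
  unlink(dir, recursive = TRUE)
})
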