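test_that("single-component fit is the closed-form MLE, robust to constants", {
  x <- c(1.1, 1.3, 0.9, 1.0, 1.2, rep(1.05, 20))
  f <- fit_gaussian_mixture(x, k = 1)
  expect_equal(f$mu, mean(x))
  expect_equal(f$sigma, stats::sd(x) * sqrt((length(x) - 1) / length(x)))
  expect_equal(f$bic, -2 * f$loglik + 2 * log(length(x)))

  const <- fit_gaussian_mixture(rep(2.5, 30), k = 1)
  expect_equal(const$mu, 2.5)
  expect_gt(const$sigma, 0)
  expect_identical(const, fit_gaussian_mixture(rep(2.5, 30), k = 1))
})

test_that("EM recovers well-separated two-component parameters", {
  set.seed(3)
  x <- c(stats::rnorm(5000, 1.0, 0.05), stats::rnorm(5000, 1.6, 0.10))
  f <- fit_gaussian_mixture(x, k = 2, seed = 3)
  expect_lt(abs(f$mu[1] - 1.0), 0.02)
  expect_lt(abs(f$mu[2] - 1.6), 0.02)
  expect_equal(sum(f$pi), 1, tolerance = 1e-9)
  expect_true(all(f$sigma > 0))
  expect_lt(f$mu[1], f$mu[2])
})

test_that("two-component log-likelihood dominates one-component, EM is monotone", {
  set.seed(41)
  for (r in 1:5) {
    x <- stats::rnorm(200, 1, 0.1) + (stats::runif(200) < 0.3) * stats::rnorm(200, 0.5, 0.1)
    f1 <- fit_gaussian_mixture(x, k = 1)
    f2 <- fit_gaussian_mixture(x, k = 2, seed = r)
    expect_gte(f2$loglik, f1$loglik - 1e-8)
    expect_true(all(diff(f2$ll_trace) >= -1e-7))
  }
})

test_that("model selection penalizes ties and recognizes real mixtures", {
  set.seed(8)
  uni <- stats::rnorm(2000, 1.1, 0.1)
  s_uni <- select_binding_model(fit_gaussian_mixture(uni, k = 1),
                                fit_gaussian_mixture(uni, k = 2, seed = 1))
  expect_false(s_uni$retained)

  # identical log-likelihoods: the 2-component model loses by its penalty
  f1 <- structure(list(k = 1L, loglik = -100, n = 500,
                       bic = 200 + 2 * log(500), mu = 1, sigma = 0.1),
                  class = "gaussian_mixture")
  f2 <- structure(list(k = 2L, loglik = -100, n = 500,
                       bic = 200 + 5 * log(500), mu = c(1, 1.5),
                       sigma = c(0.1, 0.1)),
                  class = "gaussian_mixture")
  expect_false(select_binding_model(f1, f2)$retained)

  # coincident component means are treated as unimodal even if BIC prefers k=2
  f2_tie <- f2
  f2_tie$mu <- c(1, 1)
  f2_tie$bic <- 100
  expect_false(select_binding_model(f1, f2_tie)$retained)

  # well-separated mixture at large n is retained
  set.seed(9)
  mix <- c(stats::rnorm(5000, 1.0, 0.1), stats::rnorm(5000, 1.5, 0.1))
  s_mix <- select_binding_model(fit_gaussian_mixture(mix, k = 1),
                                fit_gaussian_mixture(mix, k = 2, seed = 2))
  expect_true(s_mix$retained)

  f_bad <- fit_gaussian_mixture(mix[1:2000], k = 1)
  expect_error(select_binding_model(f_bad,
                                    fit_gaussian_mixture(mix, k = 2, seed = 2)),
               "same data")
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(12)
  x <- c(stats::rnorm(1500, 1.05, 0.08), stats::rnorm(700, 1.55, 0.15))
  f <- fit_gaussian_mixture(x, k = 2, seed = 12)
  m <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(f$loglik - m$loglik), 0.05)
  expect_equal(f$mu, sort(as.numeric(m$parameters$mean)), tolerance = 0.01)
})

test_that("insufficient or non-finite data are rejected", {
  expect_error(fit_gaussian_mixture(stats::rnorm(10), k = 2), "at least 20")
  expect_error(fit_gaussian_mixture(c(stats::rnorm(30), NA), k = 1), "finite")
  expect_error(fit_gaussian_mixture(stats::rnorm(30), k = 3), "1 or 2")
})

test_that("TPI transform matches direct normal-CDF evaluation", {
  m <- structure(list(k = 2L, mu = c(1.0, 1.5), sigma = c(0.1, 0.1),
                      pi = c(0.5, 0.5)), class = "gaussian_mixture")
  expect_equal(tpi_transform(1.25, m), 0, tolerance = 1e-12)

  m2 <- structure(list(k = 2L, mu = c(1.0, 1.5), sigma = c(0.1, 0.2),
                       pi = c(0.5, 0.5)), class = "gaussian_mixture")
  # F_p(1.2) = Phi((1.2-1.5)/0.2) = Phi(-1.5); F_n(1.2) = Phi((1.2-1.0)/0.1) = Phi(2)
  expect_equal(tpi_transform(1.2, m2),
               stats::pnorm(-1.5) + stats::pnorm(2.0) - 1, tolerance = 1e-12)
  expect_equal(tpi_transform(1.2, m2), 0.04405707, tolerance = 1e-7)

  expect_lt(abs(tpi_transform(1.0 - 10 * 0.1, m2) - (-1)), 1e-6)

  # component storage order must not matter
  m2_swapped <- m2
  m2_swapped$mu <- rev(m2$mu)
  m2_swapped$sigma <- rev(m2$sigma)
  expect_equal(tpi_transform(1.2, m2_swapped), tpi_transform(1.2, m2))
})

test_that("TPI is strictly increasing and bounded on a dense grid", {
  set.seed(21)
  for (r in 1:3) {
    mu_n <- stats::runif(1, 0.9, 1.1)
    m <- structure(list(k = 2L, mu = c(mu_n, mu_n + stats::runif(1, 0.3, 0.7)),
                        sigma = stats::runif(2, 0.05, 0.2),
                        pi = c(0.6, 0.4)), class = "gaussian_mixture")
    grid <- seq(m$mu[1] - 5 * m$sigma[1], m$mu[2] + 5 * m$sigma[2],
                length.out = 1000)
    v <- tpi_transform(grid, m)
    expect_true(all(diff(v) > 0))
    expect_true(all(v > -1 + 1e-12 & v < 1 - 1e-12))
  }
})

test_that("TPI tables cover exactly the retained regions and preserve order", {
  st <- small_stages()
  expect_identical(dim(st$tpi),
                   c(nrow(st$cohort$suvr), length(st$retained)))
  expect_identical(colnames(st$tpi), st$retained)
  expect_true(all(st$tpi > -1 & st$tpi < 1))

  # monotone subjects: dominance in SUVR implies dominance in TPI
  suvr2 <- st$cohort$suvr
  a <- rownames(suvr2)[1]; b <- rownames(suvr2)[2]
  suvr2[a, ] <- pmax(st$cohort$suvr[a, ], st$cohort$suvr[b, ]) + 0.01
  tpi2 <- build_tpi_table(suvr2, st$models)
  expect_true(all(tpi2[a, ] >= tpi2[b, ]))

  suvr3 <- st$cohort$suvr
  suvr3[3, st$retained[1]] <- NA
  expect_error(build_tpi_table(suvr3, st$models), "missing SUVR")

  excluded <- setdiff(colnames(st$cohort$suvr), st$retained)[1]
  expect_error(tpi_transform(1.2, st$models$fits[[excluded]]), "excluded")
})

test_that("the binding-model step recovers the generator's unimodal split", {
  # at this cohort size a unimodal region is occasionally over-fitted by the
  # 2-component model, but no true mixture region may ever be excluded
  st <- medium_stages()
  truth_uni <- st$cohort$truth$unimodal
  sel <- st$models$summary
  excluded <- sel$region[!sel$retained]
  expect_true(all(truth_uni[excluded]))
  expect_gte(length(excluded), sum(truth_uni) - 2L)
  expect_true(all(sel$retained[!truth_uni[sel$region]]))
})
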