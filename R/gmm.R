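#' Fit a one- or two-component Gaussian mixture by maximum likelihood
#'
#' The single-component fit is the closed-form Gaussian MLE. The
#' two-component fit runs EM initialized by a median split, with `n_restarts`
#' additional starts from perturbed means, keeping the best log-likelihood.
#' Component SDs are floored at `sqrt(var_floor_frac * var(x))`; a restart
#' whose component collapses onto the floor is retried, and if every start
#' collapses the floored fit is returned with a warning.
#'
#' @param x numeric vector of observations (finite).
#' @param k number of components, 1 or 2.
#' @param tol EM convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations per start.
#' @param n_restarts number of perturbed restarts beyond the median-split start.
#' @param var_floor_frac variance floor as a fraction of the sample variance.
#' @param min_n minimum number of observations required.
#' @param seed optional seed for the restart perturbations.
#' @return object of class `gaussian_mixture`: list with `k`, `pi`, `mu`,
#'   `sigma` (components sorted by ascending mean), `loglik`, `ll_trace`
#'   (per-iteration log-likelihoods of the winning start), `n`, `bic`,
#'   `converged`.
#' @export
fit_gaussian_mixture <- function(x, k = 2, tol = 1e-8, max_iter = 500,
                                 n_restarts = 5, var_floor_frac = 1e-6,
                                 min_n = 20, seed = NULL) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  n <- length(x)
  if (n < min_n)
    stop(sprintf("need at least %d observations, got %d", min_n, n),
         call. = FALSE)
  if (!k %in% c(1, 2)) stop("`k` must be 1 or 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  v <- stats::var(x)
  floor_sd <- sqrt(max(var_floor_frac * v, 1e-12))

  if (k == 1) {
    mu <- mean(x)
    sd_mle <- sqrt(max(v * (n - 1) / n, floor_sd^2))
    ll <- sum(stats::dnorm(x, mu, sd_mle, log = TRUE))
    return(structure(list(k = 1L, pi = 1, mu = mu, sigma = sd_mle,
                          loglik = ll, ll_trace = ll, n = n,
                          bic = -2 * ll + 2 * log(n), converged = TRUE),
                     class = "gaussian_mixture"))
  }

  em_once <- function(mu, sg, p1) {
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    collapsed <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- p1 * stats::dnorm(x, mu[1], sg[1])
      d2 <- (1 - p1) * stats::dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot < 1e-300] <- 1e-300
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      g1 <- d1 / tot
      s1 <- sum(g1); s2 <- n - s1
      if (s1 < 1e-8 || s2 < 1e-8) { collapsed <- TRUE; break }
      p1 <- s1 / n
      mu[1] <- sum(g1 * x) / s1
      mu[2] <- sum((1 - g1) * x) / s2
      sg[1] <- sqrt(sum(g1 * (x - mu[1])^2) / s1)
      sg[2] <- sqrt(sum((1 - g1) * (x - mu[2])^2) / s2)
      if (any(sg < floor_sd)) collapsed <- TRUE
      sg <- pmax(sg, floor_sd)
    }
    list(pi = c(p1, 1 - p1), mu = mu, sigma = sg, loglik = ll,
         ll_trace = ll_trace, converged = converged, collapsed = collapsed)
  }

  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0) hi <- lo
  sd0 <- max(stats::sd(x) / 2, floor_sd)
  starts <- list(list(mu = c(mean(lo), mean(hi)),
                      sg = c(max(stats::sd(lo), floor_sd, na.rm = TRUE),
                             max(stats::sd(hi), floor_sd, na.rm = TRUE)),
                      p1 = 0.5))
  for (r in seq_len(n_restarts)) {
    starts[[r + 1]] <- list(mu = sort(stats::rnorm(2, mean(x), stats::sd(x) + floor_sd)),
                            sg = c(sd0, sd0), p1 = stats::runif(1, 0.2, 0.8))
  }

  best <- NULL
  any_clean <- FALSE
  for (st in starts) {
    fit <- tryCatch(em_once(st$mu, st$sg, st$p1), error = function(e) NULL)
    if (is.null(fit)) next
    if (!fit$collapsed) any_clean <- TRUE
    if (is.null(best) ||
        (!fit$collapsed && best$collapsed) ||
        (fit$collapsed == best$collapsed && fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("EM failed on all starts", call. = FALSE)
  if (!any_clean)
    warning("all EM starts collapsed; returning variance-floored fit")

  ord <- order(best$mu)
  structure(list(k = 2L, pi = best$pi[ord], mu = best$mu[ord],
                 sigma = best$sigma[ord], loglik = best$loglik,
                 ll_trace = best$ll_trace, n = n,
                 bic = -2 * best$loglik + 5 * log(n),
                 converged = best$converged,
                 collapsed = best$collapsed),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture (k = %d, n = %d): loglik = %.3f, BIC = %.3f\n",
              x$k, x$n, x$loglik, x$bic))
  for (i in seq_len(x$k))
    cat(sprintf("  component %d: pi = %.3f, mu = %.4f, sigma = %.4f\n",
                i, x$pi[i], x$mu[i], x$sigma[i]))
  invisible(x)
}

#' Decide whether a region shows specific (bimodal) tracer binding
#'
#' A region is retained when the two-component model has the lower BIC;
#' otherwise (including the degenerate case of coincident component means) it
#' is excluded as showing only non-specific binding. AIC is available as an
#' alternative criterion.
#'
#' @param one_fit,two_fit `gaussian_mixture` fits of the same data with
#'   `k = 1` and `k = 2`.
#' @param criterion "bic" (default) or "aic".
#' @return list with `retained` (logical), `criterion`, and the two
#'   information-criterion values.
#' @export
select_binding_model <- function(one_fit, two_fit, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(one_fit, "gaussian_mixture"),
            inherits(two_fit, "gaussian_mixture"))
  if (one_fit$n != two_fit$n)
    stop("fits were not computed on the same data (n differs)", call. = FALSE)
  ic1 <- if (criterion == "bic") one_fit$bic else -2 * one_fit$loglik + 2 * 2
  ic2 <- if (criterion == "bic") two_fit$bic else -2 * two_fit$loglik + 2 * 5
  mean_tie <- abs(diff(two_fit$mu)) < 1e-10
  # a variance-collapsed second component is a degenerate spike, not a
  # pathologic distribution: such regions count as unimodal
  degenerate <- isTRUE(two_fit$collapsed)
  list(retained = (ic2 < ic1) && !mean_tie && !degenerate,
       criterion = criterion, ic_one = ic1, ic_two = ic2)
}

#' Fit per-region Gaussian mixtures over a pooled cohort
#'
#' Pools all subjects within each region, fits one- and two-component models,
#' and applies [select_binding_model()] to flag non-specific-binding regions.
#' In retained regions the higher-mean component is labeled pathologic and the
#' lower-mean component non-pathologic.
#'
#' @param suvr subjects-by-regions SUVR matrix.
#' @param criterion model-selection criterion passed to [select_binding_model()].
#' @param seed seed for EM restarts (one stream across regions).
#' @param ... further arguments passed to [fit_gaussian_mixture()].
#' @return object of class `region_mixtures`: list with `summary` (data frame:
#'   region, retained, BICs, component parameters) and `fits` (per-region list
#'   with `one`, `two`, `retained`).
#' @export
fit_region_mixtures <- function(suvr, criterion = "bic", seed = 11L, ...) {
  stopifnot(is.matrix(suvr))
  set.seed(seed)
  regions <- colnames(suvr)
  fits <- vector("list", length(regions))
  names(fits) <- regions
  rows <- vector("list", length(regions))
  for (j in seq_along(regions)) {
    x <- suvr[, j]
    f1 <- fit_gaussian_mixture(x, k = 1, ...)
    f2 <- fit_gaussian_mixture(x, k = 2, ...)
    sel <- select_binding_model(f1, f2, criterion = criterion)
    fits[[j]] <- list(one = f1, two = f2, retained = sel$retained)
    rows[[j]] <- data.frame(
      region = regions[j], retained = sel$retained,
      ic_one = sel$ic_one, ic_two = sel$ic_two,
      pi_n = f2$pi[1], mu_n = f2$mu[1], sigma_n = f2$sigma[1],
      pi_p = f2$pi[2], mu_p = f2$mu[2], sigma_p = f2$sigma[2],
      n = f1$n, stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, rows), fits = fits,
                 criterion = criterion),
            class = "region_mixtures")
}

#' @export
print.region_mixtures <- function(x, ...) {
  cat(sprintf("Per-region Gaussian mixtures (%s selection): %d retained, %d excluded of %d regions\n",
              toupper(x$criterion), sum(x$summary$retained),
              sum(!x$summary$retained), nrow(x$summary)))
  invisible(x)
}

#' Regions retained by the binding-model selection
#' @param models a `region_mixtures` object.
#' @return character vector of retained region labels.
#' @export
retained_regions <- function(models) {
  models$summary$region[models$summary$retained]
}

#' Transform SUVR to the tau pathology index (TPI)
#'
#' For a retained region with pathologic (higher-mean) component CDF `F_p` and
#' non-pathologic component CDF `F_n`, `TPI(x) = F_p(x) - (1 - F_n(x))`, i.e.
#' the percentile on the pathologic curve minus the complement of the
#' percentile on the non-pathologic curve. TPI is strictly increasing in SUVR
#' and bounded in (-1, 1): values far below both components map near -1 and
#' values far above both map near +1.
#'
#' @param x SUVR value(s).
#' @param model a retained two-component `gaussian_mixture` (or the per-region
#'   entry of a `region_mixtures` object).
#' @return numeric vector of TPI values.
#' @export
tpi_transform <- function(x, model) {
  if (is.list(model) && !inherits(model, "gaussian_mixture")) {
    if (isFALSE(model$retained))
      stop("TPI is undefined for an excluded (non-specific-binding) region",
           call. = FALSE)
    model <- model$two
  }
  stopifnot(inherits(model, "gaussian_mixture"), model$k == 2L)
  # pathologic = higher-mean component, regardless of storage order
  p <- which.max(model$mu)
  n <- which.min(model$mu)
  stats::pnorm(x, model$mu[p], model$sigma[p]) +
    stats::pnorm(x, model$mu[n], model$sigma[n]) - 1
}

#' Build the TPI table for a cohort
#'
#' Applies [tpi_transform()] element-wise over retained regions; excluded
#' regions are dropped. The mixture models may come from a larger pooled
#' cohort than the subjects being transformed.
#'
#' @param suvr subjects-by-regions SUVR matrix.
#' @param models a `region_mixtures` object.
#' @return subjects-by-retained-regions TPI matrix.
#' @export
build_tpi_table <- function(suvr, models) {
  stopifnot(is.matrix(suvr), inherits(models, "region_mixtures"))
  keep <- retained_regions(models)
  missing_regions <- setdiff(keep, colnames(suvr))
  if (length(missing_regions) > 0)
    stop("SUVR table lacks retained region(s): ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  out <- matrix(NA_real_, nrow(suvr), length(keep),
                dimnames = list(rownames(suvr), keep))
  for (r in keep) {
    x <- suvr[, r]
    if (anyNA(x))
      stop(sprintf("missing SUVR for subject %s in region %s",
                   rownames(suvr)[which(is.na(x))[1]], r), call. = FALSE)
    out[, r] <- tpi_transform(x, models$fits[[r]])
  }
  out
}
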