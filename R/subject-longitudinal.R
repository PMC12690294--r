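#' Pool training coefficients across folds
#'
#' Arithmetic mean of the per-fold training intercepts and slopes for one
#' variant (by default from the amyloid-positive training splits, the set the
#' subject-level analyses use).
#'
#' @param fit a `tau_spread` object.
#' @param variant model variant.
#' @param subset training subset to pool over (default `"abpos"`).
#' @return named vector `c(intercept, slope)`.
#' @export
average_fold_models <- function(fit, variant, subset = "abpos") {
  tr <- fit$results[fit$results$subset == subset &
                      fit$results$role == "train" &
                      fit$results$variant == variant, ]
  if (nrow(tr) < fit$k)
    stop(sprintf("missing training folds for variant %s", variant),
         call. = FALSE)
  c(intercept = mean(tr$intercept), slope = mean(tr$slope))
}

#' Subject-level effect size of a distance model
#'
#' Cross-sectional: the pooled model's predictions (from the subject's own
#' distance profile) are regressed against the subject's measured TPI and the
#' standardized beta extracted. Longitudinal: annualized TPI change is
#' regressed on predicted change with baseline TPI as a covariate, and the
#' standardized beta of the prediction term extracted.
#'
#' @param measured the subject's measured vector over retained regions (TPI,
#'   or annualized TPI change).
#' @param distance the subject's distance profile for the variant.
#' @param pooled_model `c(intercept, slope)` from [average_fold_models()], or
#'   a coefficient vector of length 3 (`intercept, slope, baseline`) for the
#'   longitudinal models.
#' @param baseline optional baseline TPI vector; triggers the longitudinal
#'   form.
#' @return list with `beta_std`, `t`, `p`, `n`, `analysis`, or
#'   `beta_std = NA` with a `reason` when predictions are degenerate.
#' @export
subject_effect_size <- function(measured, distance, pooled_model,
                                baseline = NULL) {
  stopifnot(length(measured) == length(distance))
  if (is.null(baseline)) {
    pred <- pooled_model[["intercept"]] + pooled_model[["slope"]] * distance
    if (stats::sd(pred) == 0 || stats::sd(measured) == 0)
      return(list(beta_std = NA_real_, reason = "zero-variance predictions",
                  analysis = "cross-sectional", n = length(measured)))
    f <- reg_row(measured, pred)
    return(list(beta_std = f$beta_std, t = f$t, p = f$p, n = f$n,
                analysis = "cross-sectional"))
  }
  stopifnot(length(baseline) == length(measured))
  pred <- pooled_model[[1]] + pooled_model[[2]] * distance +
    pooled_model[[3]] * baseline
  if (stats::sd(pred) == 0)
    return(list(beta_std = NA_real_, reason = "zero-variance predictions",
                analysis = "longitudinal", n = length(measured)))
  fit <- stats::lm(scale(measured) ~ scale(pred) + scale(baseline))
  sm <- summary(fit)$coefficients
  list(beta_std = unname(stats::coef(fit)[2]),
       t = unname(sm[2, "t value"]), p = unname(sm[2, "Pr(>|t|)"]),
       n = length(measured), analysis = "longitudinal")
}

#' Compare per-subject effect sizes across the four variants
#'
#' One-way repeated-measures ANOVA over the subjects-by-variants matrix of
#' standardized betas, with Bonferroni-corrected pairwise paired t-tests.
#'
#' @param effects subjects-by-variants numeric matrix.
#' @return output of [rm_anova_oneway()].
#' @export
compare_effect_sizes <- function(effects) {
  rm_anova_oneway(effects)
}

#' Annualized change in TPI
#'
#' @param baseline,followup subjects-by-regions TPI matrices over the same
#'   regions; `followup` may cover a subset of the baseline subjects.
#' @param intervals named vector of inter-scan intervals in years (> 0).
#' @return list with `annualized` (matrix of (follow-up - baseline)/interval),
#'   `baseline`, `intervals`.
#' @export
annualize_change <- function(baseline, followup, intervals) {
  stopifnot(identical(colnames(baseline), colnames(followup)))
  ids <- rownames(followup)
  if (!all(ids %in% rownames(baseline)))
    stop("follow-up subjects missing from the baseline table", call. = FALSE)
  iv <- intervals[ids]
  if (any(is.na(iv) | iv <= 0))
    stop("intervals must be positive for all follow-up subjects", call. = FALSE)
  ann <- sweep(followup - baseline[ids, , drop = FALSE], 1, iv, "/")
  list(annualized = ann, baseline = baseline[ids, , drop = FALSE],
       intervals = iv)
}

#' Group-level longitudinal distance model
#'
#' Two-predictor OLS of rank-averaged annualized TPI change on average
#' distance from epicenters and baseline TPI; the distance term is the
#' quantity of interest and is reported as a standardized beta with a 95%
#' confidence interval.
#'
#' @param delta_tpi mean annualized TPI change by rank.
#' @param distance mean distance by rank.
#' @param baseline mean baseline TPI by rank.
#' @return list with `beta_std` (distance), `ci` (95% CI on the standardized
#'   distance beta), `t`, `p`, `beta_baseline`, `r2`, `df`, `coefficients`
#'   (unstandardized, for prediction).
#' @export
fit_longitudinal_group_model <- function(delta_tpi, distance, baseline) {
  stopifnot(length(delta_tpi) == length(distance),
            length(delta_tpi) == length(baseline))
  if (abs(stats::cor(distance, baseline)) > 0.999)
    stop("degenerate fit: distance and baseline are collinear", call. = FALSE)
  fit <- stats::lm(delta_tpi ~ distance + baseline)
  zfit <- stats::lm(scale(delta_tpi) ~ scale(distance) + scale(baseline))
  sm <- summary(zfit)$coefficients
  ci <- stats::confint(zfit)[2, ]
  list(beta_std = unname(stats::coef(zfit)[2]), ci = unname(ci),
       t = unname(sm[2, "t value"]), p = unname(sm[2, "Pr(>|t|)"]),
       beta_baseline = unname(stats::coef(zfit)[3]),
       r2 = summary(fit)$r.squared,
       df = length(delta_tpi) - 3L,
       coefficients = stats::coef(fit))
}

#' Compare the longitudinal distance terms of the variants (Hittner's Z)
#'
#' The shared outcome is the rank-averaged annualized TPI change residualized
#' on baseline TPI. Each variant's distance vector is correlated with this
#' outcome and the reference variant's correlation is compared with each
#' other variant's by [hittner_z()]. Semipartial correlations (distance
#' residualized on baseline too) are available by flag and reported alongside.
#'
#' @param delta_tpi,baseline rank-averaged outcome and covariate vectors.
#' @param distances named list of rank-averaged distance vectors (one per
#'   variant).
#' @param reference the variant each other variant is compared against.
#' @param semipartial also residualize each distance vector on baseline.
#' @return data frame: comparison, r_ref, r_other, r_between, z, p.
#' @export
compare_longitudinal_models <- function(delta_tpi, baseline, distances,
                                        reference = "IE-IC",
                                        semipartial = FALSE) {
  stopifnot(reference %in% names(distances))
  outcome <- stats::residuals(stats::lm(delta_tpi ~ baseline))
  dvec <- distances
  if (semipartial)
    dvec <- lapply(distances, function(d)
      stats::residuals(stats::lm(d ~ baseline)))
  n <- length(outcome)
  others <- setdiff(names(dvec), reference)
  do.call(rbind, lapply(others, function(v) {
    r1 <- stats::cor(outcome, dvec[[reference]])
    r2 <- stats::cor(outcome, dvec[[v]])
    r12 <- stats::cor(dvec[[reference]], dvec[[v]])
    if (r12 > 1 - 1e-12 && abs(r1 - r2) < 1e-12) {
      # identical predictors: the comparison is exactly null
      hz <- list(z = 0, p = 1)
    } else {
      hz <- hittner_z(r1, r2, r12, n)
    }
    data.frame(comparison = paste(reference, "vs", v),
               r_ref = r1, r_other = r2, r_between = r12,
               z = hz$z, p = hz$p, stringsAsFactors = FALSE)
  }))
}

#' Longitudinal analysis of tau accumulation for all four variants
#'
#' Rank-aligns each longitudinal subject by baseline TPI, averages annualized
#' TPI change, baseline TPI, and the four distance profiles across subjects by
#' rank, fits the two-predictor longitudinal model per variant, compares the
#' distance terms against the fully individualized variant with Hittner's Z,
#' and computes subject-level longitudinal effect sizes with their
#' repeated-measures comparison.
#'
#' @param tpi_baseline subjects-by-retained-regions baseline TPI matrix (the
#'   full cohort; only follow-up subjects are used).
#' @param annualized output of [annualize_change()].
#' @param profiles the four distance-profile matrices.
#' @param rank_on `"baseline"` (default) aligns subjects by baseline TPI
#'   rank, keeping the same permutation the cross-sectional models use;
#'   `"change"` aligns by annualized-change rank instead.
#' @return object of class `tau_spread_long`: list with `group` (per-variant
#'   fits), `comparisons` (Hittner table), `subject_effects`
#'   (subjects-by-variants beta matrix), `anova`, `n_subjects`.
#' @export
longitudinal_analysis <- function(tpi_baseline, annualized, profiles,
                                  rank_on = c("baseline", "change")) {
  rank_on <- match.arg(rank_on)
  ids <- rownames(annualized$annualized)
  ids <- ids[!vapply(ids, function(id)
    anyNA(profiles[["IE-IC"]][id, ]), logical(1))]
  if (length(ids) < 4) stop("too few longitudinal subjects", call. = FALSE)
  R <- ncol(tpi_baseline)

  base_m <- matrix(NA_real_, length(ids), R)
  delta_m <- matrix(NA_real_, length(ids), R)
  dist_m <- lapply(profiles, function(p) matrix(NA_real_, length(ids), R))
  for (i in seq_along(ids)) {
    id <- ids[i]
    key <- if (rank_on == "baseline") tpi_baseline[id, ]
           else annualized$annualized[id, ]
    perm <- order(-key, colnames(tpi_baseline))
    base_m[i, ] <- tpi_baseline[id, perm]
    delta_m[i, ] <- annualized$annualized[id, perm]
    for (v in names(profiles)) dist_m[[v]][i, ] <- profiles[[v]][id, perm]
  }
  base_v <- colMeans(base_m)
  delta_v <- colMeans(delta_m)
  dist_v <- lapply(dist_m, colMeans)

  group <- lapply(variant_names(), function(v)
    fit_longitudinal_group_model(delta_v, dist_v[[v]], base_v))
  names(group) <- variant_names()

  comparisons <- compare_longitudinal_models(delta_v, base_v, dist_v)

  effects <- matrix(NA_real_, length(ids), length(variant_names()),
                    dimnames = list(ids, variant_names()))
  for (v in variant_names()) {
    cf <- group[[v]]$coefficients
    for (i in seq_along(ids)) {
      id <- ids[i]
      se <- subject_effect_size(annualized$annualized[id, ],
                                profiles[[v]][id, ], cf,
                                baseline = tpi_baseline[id, ])
      effects[i, v] <- se$beta_std
    }
  }
  anova <- tryCatch(compare_effect_sizes(effects), error = function(e) NULL)

  structure(list(group = group, comparisons = comparisons,
                 subject_effects = effects, anova = anova,
                 n_subjects = length(ids)),
            class = "tau_spread_long")
}

#' @export
print.tau_spread_long <- function(x, ...) {
  cat(sprintf("Longitudinal tau-spread analysis (%d subjects)\n", x$n_subjects))
  for (v in names(x$group))
    cat(sprintf("  %-6s distance beta_std = %6.3f [%.3f, %.3f], R^2 = %.3f\n",
                v, x$group[[v]]$beta_std, x$group[[v]]$ci[1],
                x$group[[v]]$ci[2], x$group[[v]]$r2))
  invisible(x)
}

#' Subject-level cross-sectional effect sizes for all variants
#'
#' Applies the pooled amyloid-positive training models at the single-subject
#' level and extracts each subject's standardized beta per variant, with the
#' repeated-measures comparison across variants.
#'
#' @param fit a `tau_spread` object.
#' @param tpi subjects-by-retained-regions TPI matrix.
#' @param profiles the four distance-profile matrices.
#' @param subjects subject ids to evaluate (default: included amyloid-positive
#'   subjects is the caller's responsibility; defaults to `fit$included`).
#' @return list with `effects` (subjects-by-variants matrix) and `anova`.
#' @export
subject_level_analysis <- function(fit, tpi, profiles,
                                   subjects = fit$included) {
  subjects <- subjects[!vapply(subjects, function(id)
    anyNA(profiles[["IE-IC"]][id, ]), logical(1))]
  effects <- matrix(NA_real_, length(subjects), length(variant_names()),
                    dimnames = list(subjects, variant_names()))
  for (v in variant_names()) {
    pm <- average_fold_models(fit, v)
    for (id in subjects) {
      se <- subject_effect_size(tpi[id, ], profiles[[v]][id, ], pm)
      effects[id, v] <- se$beta_std
    }
  }
  anova <- tryCatch(compare_effect_sizes(effects), error = function(e) NULL)
  list(effects = effects, anova = anova)
}
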