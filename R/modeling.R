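#' Residualize TPI for nuisance covariates
#'
#' Regresses age, sex, education, race, PET-dMRI scan interval, and study out
#' of the region-level TPI values with a linear mixed model (random intercept
#' per participant), returning conditional residuals (observed minus fixed
#' effects minus the participant intercept). Falls back to fixed-effects-only
#' OLS residuals on request or when the mixed fit is singular beyond repair.
#'
#' @param tpi subjects-by-regions TPI matrix.
#' @param metadata data frame with `subject_id`, `age`, `sex`, `education`,
#'   `race`, `scan_interval`, `study`.
#' @param method `"lmm"` (default) or `"ols"`.
#' @return matrix of adjusted TPI, same shape as `tpi`.
#' @export
residualize_tpi <- function(tpi, metadata, method = c("lmm", "ols")) {
  method <- match.arg(method)
  need <- c("subject_id", "age", "sex", "education", "race",
            "scan_interval", "study")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0)
    stop("metadata lacks covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  md <- metadata[match(rownames(tpi), metadata$subject_id), ]
  for (f in need) {
    if (anyNA(md[[f]]))
      stop(sprintf("missing covariate `%s` for subject %s", f,
                   md$subject_id[which(is.na(md[[f]]))[1]]), call. = FALSE)
  }
  long <- data.frame(
    value = as.vector(tpi),
    subject_id = rep(rownames(tpi), times = ncol(tpi)),
    age = rep(md$age, times = ncol(tpi)),
    sex = rep(md$sex, times = ncol(tpi)),
    education = rep(md$education, times = ncol(tpi)),
    race = rep(md$race, times = ncol(tpi)),
    scan_interval = rep(md$scan_interval, times = ncol(tpi)),
    study = rep(md$study, times = ncol(tpi)),
    stringsAsFactors = FALSE)
  # drop constant factors (single-level factors break model.matrix)
  terms <- c("age", "sex", "education", "race", "scan_interval", "study")
  keep <- vapply(terms, function(t) length(unique(long[[t]])) > 1, logical(1))
  rhs <- paste(terms[keep], collapse = " + ")
  if (!any(keep)) rhs <- "1"

  if (method == "lmm") {
    fml <- stats::as.formula(paste("value ~", rhs, "+ (1 | subject_id)"))
    fit <- tryCatch(
      lme4::lmer(fml, data = long,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("mixed-model fit failed; using fixed-effects OLS residuals")
      return(residualize_tpi(tpi, metadata, method = "ols"))
    }
    res <- stats::residuals(fit)
  } else {
    fml <- stats::as.formula(paste("value ~", rhs))
    res <- stats::residuals(stats::lm(fml, data = long))
  }
  matrix(res, nrow(tpi), ncol(tpi), dimnames = dimnames(tpi))
}

#' Stratified k-fold assignment
#'
#' Assigns each subject to exactly one test fold, balancing the stratifying
#' variable (amyloid status by default) so per-fold stratum counts differ by
#' at most one.
#'
#' @param metadata data frame with `subject_id`.
#' @param k number of folds.
#' @param stratify name of the metadata column to balance (default
#'   `"abeta_positive"`).
#' @param seed RNG seed.
#' @return named integer vector of fold ids (1..k) indexed by subject id.
#' @export
stratified_kfold <- function(metadata, k = 5, stratify = "abeta_positive",
                             seed = 17L) {
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  set.seed(seed)
  folds <- integer(nrow(metadata))
  names(folds) <- metadata$subject_id
  for (s in unique(metadata[[stratify]])) {
    idx <- which(metadata[[stratify]] == s)
    if (length(idx) < k)
      stop(sprintf("stratum %s has fewer subjects (%d) than folds (%d)",
                   s, length(idx), k), call. = FALSE)
    folds[idx] <- (sample(seq_along(idx)) - 1L) %% k + 1L
  }
  folds
}

#' Rank-align subjects and average by rank
#'
#' For each selected subject, regions are sorted by raw TPI in descending
#' order (ties broken by region label); the same permutation is applied to
#' the adjusted TPI and to each distance profile. Values are then averaged
#' across subjects at each rank, yielding comparable group vectors despite
#' heterogeneous epicenters.
#'
#' @param tpi_raw,tpi_adj subjects-by-regions matrices (raw TPI drives the
#'   ranking; adjusted TPI is averaged).
#' @param profiles list of subjects-by-regions distance matrices (the four
#'   variants from [epicenter_distance_profiles()]).
#' @param subjects subject ids to include.
#' @return list with `tpi` (mean adjusted TPI by rank), `dist` (list of mean
#'   distance by rank per variant), `n_subjects`, and `permutations`.
#' @export
rank_align_and_average <- function(tpi_raw, tpi_adj, profiles, subjects) {
  usable <- subjects
  for (v in names(profiles)) {
    bad <- usable[apply(profiles[[v]][usable, , drop = FALSE], 1, anyNA)]
    if (length(bad) > 0) {
      warning(sprintf("excluding %d subject(s) lacking a %s profile",
                      length(bad), v))
      usable <- setdiff(usable, bad)
    }
  }
  if (length(usable) == 0) stop("no usable subjects", call. = FALSE)
  R <- ncol(tpi_raw)
  perms <- matrix(NA_integer_, length(usable), R,
                  dimnames = list(usable, NULL))
  adj_mat <- matrix(NA_real_, length(usable), R)
  dist_mats <- lapply(profiles, function(p) matrix(NA_real_, length(usable), R))
  for (i in seq_along(usable)) {
    id <- usable[i]
    perm <- order(-tpi_raw[id, ], colnames(tpi_raw))
    perms[i, ] <- perm
    adj_mat[i, ] <- tpi_adj[id, perm]
    for (v in names(profiles))
      dist_mats[[v]][i, ] <- profiles[[v]][id, perm]
  }
  list(tpi = colMeans(adj_mat),
       dist = lapply(dist_mats, colMeans),
       n_subjects = length(usable),
       permutations = perms)
}

reg_row <- function(y, x) {
  if (stats::sd(x) == 0)
    stop("degenerate fit: predictor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  n <- length(y)
  list(fit = fit,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       beta_std = unname(stats::coef(fit)[2] * stats::sd(x) / stats::sd(y)),
       t = unname(sm$coefficients[2, "t value"]),
       p = unname(sm$coefficients[2, "Pr(>|t|)"]),
       df = n - 2L,
       r2 = sm$r.squared,
       adj_r2 = sm$adj.r.squared,
       rmse = sqrt(mean(stats::residuals(fit)^2)),
       n = n)
}

#' Fit one group-level distance-TPI regression
#'
#' OLS of rank-averaged TPI on rank-averaged distance from epicenters. With a
#' `group` factor the stacked interaction model
#' `tpi ~ distance * group` is fitted and the interaction term reported.
#'
#' @param tpi mean adjusted TPI by rank.
#' @param distance mean distance by rank.
#' @param group optional factor (same length) for the interaction model.
#' @return list of regression summaries (standardized beta, t, p, df, R^2,
#'   adjusted R^2, RMSE); with `group`, also `interaction_t`, `interaction_p`.
#' @export
fit_group_model <- function(tpi, distance, group = NULL) {
  stopifnot(length(tpi) == length(distance))
  out <- reg_row(tpi, distance)
  if (!is.null(group)) {
    g <- as.factor(group)
    fit <- stats::lm(tpi ~ distance * g)
    sm <- summary(fit)$coefficients
    row <- grep("^distance:", rownames(sm))
    out$interaction_t <- unname(sm[row, "t value"])
    out$interaction_p <- unname(sm[row, "Pr(>|t|)"])
  }
  out
}

#' Evaluate a trained distance model on held-out rank-averaged data
#'
#' Predicts TPI from the training coefficients applied to the test distances,
#' then regresses measured TPI on the predictions; a working model yields a
#' positive standardized beta.
#'
#' @param train a fit from [fit_group_model()].
#' @param tpi_test,distance_test held-out rank-averaged vectors.
#' @return regression summary list (role: test).
#' @export
evaluate_model <- function(train, tpi_test, distance_test) {
  stopifnot(length(tpi_test) == length(distance_test))
  pred <- train$intercept + train$slope * distance_test
  if (stats::sd(pred) == 0)
    stop("degenerate fit: constant predictions (zero training slope)",
         call. = FALSE)
  reg_row(tpi_test, pred)
}

#' Paired t-tests of per-fold R-squared between model variants
#'
#' @param r2 folds-by-variants matrix of R-squared values.
#' @return data frame with one row per variant pair: t, df, p (two-sided).
#'   Constant nonzero differences are reported as infinite t with p = 0 and a
#'   warning.
#' @export
compare_folds <- function(r2) {
  r2 <- as.matrix(r2)
  if (nrow(r2) < 2) stop("need at least 2 folds", call. = FALSE)
  pairs <- utils::combn(ncol(r2), 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- r2[, a] - r2[, b]
    if (stats::sd(d) == 0) {
      if (mean(d) != 0)
        warning("constant nonzero R^2 difference; t reported as infinite")
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(r2[, a], r2[, b], paired = TRUE)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(pair = paste(colnames(r2)[c(a, b)], collapse = " vs "),
               t = t, df = nrow(r2) - 1L, p = p, stringsAsFactors = FALSE)
  }))
}

variant_names <- function() c("IE-IC", "IE-GC", "GE-IC", "GE-GC")

#' Fit the four-variant network tau-spread model with k-fold validation
#'
#' The central estimator. Residualizes TPI for covariates, assigns stratified
#' folds, and for each fold rank-aligns and averages the training subjects,
#' fits the four distance-TPI regressions (IE-IC, IE-GC, GE-IC, GE-GC), and
#' evaluates each on the held-out fold. The same procedure is repeated within
#' the amyloid-positive and amyloid-negative subsets, and a
#' Distance-by-amyloid-status interaction is tested per fold on stacked
#' group-averaged data. Subjects with zero epicenters are excluded from all
#' statistics.
#'
#' @param tpi subjects-by-retained-regions TPI matrix.
#' @param profiles list of four distance-profile matrices from
#'   [epicenter_distance_profiles()].
#' @param metadata cohort metadata (see [residualize_tpi()]; must also carry
#'   `abeta_positive`).
#' @param epicenter_sets named list of `epicenter_set`s (used to exclude
#'   zero-epicenter subjects).
#' @param k number of folds.
#' @param seed RNG seed for the fold assignment.
#' @param residualize `"lmm"`, `"ols"`, or `"none"`.
#' @return object of class `tau_spread`: list with `results` (data frame of
#'   all train/test regressions), `comparisons` (per subset/role paired-t
#'   tables across folds), `interaction` (per variant/fold interaction
#'   tests), `folds`, `included`, and `group_vectors` (whole-sample
#'   rank-averaged vectors for plotting).
#' @export
fit_tau_spread <- function(tpi, profiles, metadata, epicenter_sets,
                           k = 5, seed = 17L,
                           residualize = c("lmm", "ols", "none")) {
  residualize <- match.arg(residualize)
  stopifnot(setequal(names(profiles), variant_names()))
  md <- metadata[match(rownames(tpi), metadata$subject_id), ]

  n_eps <- vapply(epicenter_sets[rownames(tpi)],
                  function(s) length(s$regions), integer(1))
  included <- rownames(tpi)[n_eps > 0]
  if (length(included) < 2 * k)
    stop("too few subjects with epicenters for k-fold validation", call. = FALSE)
  md_inc <- md[md$subject_id %in% included, ]

  tpi_adj <- if (residualize == "none") tpi
             else residualize_tpi(tpi, metadata, method = residualize)

  folds <- stratified_kfold(md_inc, k = k, seed = seed)

  subsets <- list(all = md_inc$subject_id,
                  abpos = md_inc$subject_id[md_inc$abeta_positive],
                  abneg = md_inc$subject_id[!md_inc$abeta_positive])

  results <- list()
  interaction <- list()
  for (subset in names(subsets)) {
    ids <- subsets[[subset]]
    for (fold in seq_len(k)) {
      train_ids <- ids[folds[ids] != fold]
      test_ids <- ids[folds[ids] == fold]
      tr <- rank_align_and_average(tpi, tpi_adj, profiles, train_ids)
      te <- rank_align_and_average(tpi, tpi_adj, profiles, test_ids)
      for (v in variant_names()) {
        f_tr <- fit_group_model(tr$tpi, tr$dist[[v]])
        f_te <- evaluate_model(f_tr, te$tpi, te$dist[[v]])
        results[[length(results) + 1]] <- data.frame(
          subset = subset, variant = v, fold = fold, role = "train",
          beta_std = f_tr$beta_std, intercept = f_tr$intercept,
          slope = f_tr$slope, t = f_tr$t, p = f_tr$p, df = f_tr$df,
          r2 = f_tr$r2, adj_r2 = f_tr$adj_r2, rmse = f_tr$rmse,
          n = f_tr$n, stringsAsFactors = FALSE)
        results[[length(results) + 1]] <- data.frame(
          subset = subset, variant = v, fold = fold, role = "test",
          beta_std = f_te$beta_std, intercept = f_te$intercept,
          slope = f_te$slope, t = f_te$t, p = f_te$p, df = f_te$df,
          r2 = f_te$r2, adj_r2 = f_te$adj_r2, rmse = f_te$rmse,
          n = f_te$n, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, results)

  # Distance x amyloid-status interaction on stacked group-averaged data
  for (fold in seq_len(k)) {
    tr_pos <- subsets$abpos[folds[subsets$abpos] != fold]
    tr_neg <- subsets$abneg[folds[subsets$abneg] != fold]
    ap <- rank_align_and_average(tpi, tpi_adj, profiles, tr_pos)
    an <- rank_align_and_average(tpi, tpi_adj, profiles, tr_neg)
    for (v in variant_names()) {
      f <- fit_group_model(c(ap$tpi, an$tpi),
                           c(ap$dist[[v]], an$dist[[v]]),
                           group = rep(c("abpos", "abneg"),
                                       c(length(ap$tpi), length(an$tpi))))
      interaction[[length(interaction) + 1]] <- data.frame(
        variant = v, fold = fold, t = f$interaction_t, p = f$interaction_p,
        stringsAsFactors = FALSE)
    }
  }
  interaction <- do.call(rbind, interaction)

  comparisons <- list()
  for (subset in names(subsets)) for (role in c("train", "test")) {
    sub <- results[results$subset == subset & results$role == role, ]
    r2m <- matrix(NA_real_, k, length(variant_names()),
                  dimnames = list(NULL, variant_names()))
    for (v in variant_names())
      r2m[, v] <- sub$r2[sub$variant == v][order(sub$fold[sub$variant == v])]
    comparisons[[paste(subset, role, sep = ".")]] <- compare_folds(r2m)
  }

  gv <- rank_align_and_average(tpi, tpi_adj, profiles, subsets$all)
  structure(list(results = results, comparisons = comparisons,
                 interaction = interaction, folds = folds,
                 included = included, k = k, seed = seed,
                 group_vectors = gv, variants = variant_names()),
            class = "tau_spread")
}

#' @export
print.tau_spread <- function(x, ...) {
  cat(sprintf("Four-variant network tau-spread model (%d subjects, %d folds)\n",
              length(x$included), x$k))
  tr <- x$results[x$results$subset == "all" & x$results$role == "train", ]
  agg <- stats::aggregate(r2 ~ variant, tr, mean)
  agg <- agg[match(x$variants, agg$variant), ]
  cat("  mean training R^2 by variant:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("    %-6s %.3f\n", agg$variant[i], agg$r2[i]))
  invisible(x)
}

#' @export
summary.tau_spread <- function(object, ...) {
  res <- object$results
  agg <- stats::aggregate(cbind(beta_std, t, r2, adj_r2, rmse) ~
                            subset + role + variant, res, mean)
  sds <- stats::aggregate(beta_std ~ subset + role + variant, res, stats::sd)
  agg$beta_sd <- sds$beta_std[match(paste(agg$subset, agg$role, agg$variant),
                                    paste(sds$subset, sds$role, sds$variant))]
  structure(list(table = agg, comparisons = object$comparisons,
                 interaction = object$interaction,
                 k = object$k, n = length(object$included)),
            class = "summary.tau_spread")
}

#' @export
print.summary.tau_spread <- function(x, ...) {
  cat(sprintf("Tau-spread model summary (%d subjects, %d folds)\n", x$n, x$k))
  cat("Mean (SD) standardized beta and mean R^2 across folds:\n")
  tb <- x$table
  tb <- tb[order(tb$subset, tb$role, tb$variant), ]
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-6s %-5s %-6s beta = %6.3f (%.3f)  R^2 = %.3f  RMSE = %.3f\n",
                tb$subset[i], tb$role[i], tb$variant[i],
                tb$beta_std[i], tb$beta_sd[i], tb$r2[i], tb$rmse[i]))
  invisible(x)
}

#' @export
coef.tau_spread <- function(object, subset = "all", ...) {
  tr <- object$results[object$results$subset == subset &
                         object$results$role == "train", ]
  agg <- stats::aggregate(cbind(intercept, slope) ~ variant, tr, mean)
  m <- as.matrix(agg[, c("intercept", "slope")])
  rownames(m) <- agg$variant
  m[object$variants, , drop = FALSE]
}

#' Predict rank-averaged TPI from distance under a fitted variant
#'
#' Applies the fold-averaged training coefficients of the chosen variant and
#' subset to new distance values.
#'
#' @param object a `tau_spread` fit.
#' @param distance numeric vector of average distances from epicenters.
#' @param variant one of `"IE-IC"`, `"IE-GC"`, `"GE-IC"`, `"GE-GC"`.
#' @param subset `"all"`, `"abpos"`, or `"abneg"`.
#' @param ... unused.
#' @return numeric vector of predicted TPI.
#' @export
predict.tau_spread <- function(object, distance, variant = "IE-IC",
                               subset = "all", ...) {
  cf <- coef(object, subset = subset)[variant, ]
  unname(cf["intercept"] + cf["slope"] * distance)
}

#' @export
plot.tau_spread <- function(x, subset = "all", ...) {
  gv <- x$group_vectors
  cf <- coef(x, subset = subset)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in x$variants) {
    graphics::plot(gv$dist[[v]], gv$tpi, pch = 19, cex = 0.6,
                   xlab = "mean distance from epicenters",
                   ylab = "mean adjusted TPI", main = v, ...)
    graphics::abline(cf[v, "intercept"], cf[v, "slope"], col = "red")
  }
  invisible(x)
}
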