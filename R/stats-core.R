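#' Compare two dependent, overlapping correlations (Hittner's Z)
#'
#' Tests whether the correlation of an outcome with predictor 1 equals its
#' correlation with predictor 2 when both are measured on the same sample.
#' Uses the Fisher-z difference divided by its standard error, with the
#' Dunn-Clark covariance of the two z-transforms evaluated at the
#' backtransformed mean of the two correlations (Hittner's modification).
#'
#' @param r_y1 correlation of the shared variable with predictor 1.
#' @param r_y2 correlation of the shared variable with predictor 2.
#' @param r_12 correlation between the two predictors.
#' @param n sample size (>= 4).
#' @return list with `z`, `p` (two-sided), the inputs, and `method`.
#' @export
hittner_z <- function(r_y1, r_y2, r_12, n) {
  rs <- c(r_y1 = r_y1, r_y2 = r_y2, r_12 = r_12)
  if (any(abs(rs) >= 1)) stop("correlations must lie in (-1, 1)", call. = FALSE)
  if (n < 4) stop("`n` must be at least 4", call. = FALSE)
  z1 <- atanh(r_y1)
  z2 <- atanh(r_y2)
  rbar <- tanh((z1 + z2) / 2)
  cov_num <- r_12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_12^2)
  c12 <- cov_num / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * c12))
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       r_y1 = r_y1, r_y2 = r_y2, r_12 = r_12, n = n,
       method = "Hittner-modified Dunn-Clark Z")
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` where MSR, MSC and
#' MSE are the row (target), column (rater) and residual mean squares of the
#' two-way ANOVA decomposition of an `n x k` ratings matrix.
#'
#' @param ratings numeric matrix, targets in rows, raters in columns, no
#'   missing cells.
#' @return list with `icc`, the three mean squares, `n`, `k`.
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must be complete", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 targets and >= 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (ss_row == 0 && ss_err == 0)
    stop("ICC undefined: no between-target variance", call. = FALSE)
  list(icc = (msr - mse) / denom, msr = msr, msc = msc, mse = mse,
       n = n, k = k)
}

#' One-way repeated-measures ANOVA with Bonferroni pairwise tests
#'
#' Subjects are the repeated factor. `F = MS_condition / MS_error` with
#' `df = (k - 1, (k - 1)(n - 1))` from the two-way (subject x condition)
#' decomposition. Pairwise paired t-tests are Bonferroni-adjusted by the
#' number of pairs actually tested (`k (k - 1) / 2`). Rows with any missing
#' cell are dropped (listwise), with the count reported.
#'
#' @param data numeric matrix, subjects in rows, conditions in columns.
#' @return list with `F`, `df1`, `df2`, `p`, `n`, `k`, `n_dropped`, and
#'   `pairwise` (data frame: pair, t, df, p_raw, p_bonferroni).
#' @export
rm_anova_oneway <- function(data) {
  data <- as.matrix(data)
  complete <- stats::complete.cases(data)
  n_dropped <- sum(!complete)
  data <- data[complete, , drop = FALSE]
  n <- nrow(data); k <- ncol(data)
  if (n < 3) stop("need at least 3 complete subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)

  grand <- mean(data)
  subj_m <- rowMeans(data); cond_m <- colMeans(data)
  ss_cond <- n * sum((cond_m - grand)^2)
  ss_subj <- k * sum((subj_m - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- as.integer(k - 1)
  df2 <- as.integer((k - 1) * (n - 1))
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  Fstat <- if (ms_err == 0) { if (ms_cond == 0) 0 else Inf } else ms_cond / ms_err
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- data[, a] - data[, b]
    if (stats::sd(d) == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      praw <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(data[, a], data[, b], paired = TRUE)
      t <- unname(tt$statistic); praw <- tt$p.value
    }
    data.frame(pair = paste(colnames(data)[c(a, b)], collapse = " vs "),
               t = t, df = n - 1, p_raw = praw,
               p_bonferroni = min(praw * n_pairs, 1),
               stringsAsFactors = FALSE)
  }))
  list(F = Fstat, df1 = df1, df2 = df2, p = p, n = n, k = k,
       n_dropped = n_dropped, pairwise = pw)
}
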