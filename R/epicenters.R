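#' Detect individualized tau epicenters by within-subject outlier analysis
#'
#' TPI values are Z-scored within each subject across retained regions
#' (sample SD, `n - 1` denominator); regions with `z >= z_threshold` are that
#' subject's epicenters. A subject whose TPI is constant (zero SD) gets an
#' empty set and a degenerate-subject warning rather than an error. Subjects
#' with zero epicenters are flagged so later statistical stages can exclude
#' them.
#'
#' @param tpi a subjects-by-regions TPI matrix, or a single named vector.
#' @param z_threshold epicenter threshold on the within-subject z-score
#'   (default 1.645, the 95th percentile of the standard normal; 1.96 and
#'   2.32 are conventional stricter choices).
#' @return for a matrix, a named list of `epicenter_set` objects; for a
#'   vector, a single `epicenter_set` (list with `subject`, `regions`,
#'   `zscores` over all regions, `threshold`, `degenerate`).
#' @export
detect_epicenters <- function(tpi, z_threshold = 1.645) {
  if (is.matrix(tpi)) {
    sets <- lapply(rownames(tpi), function(id)
      detect_epicenters_row(tpi[id, ], id, z_threshold))
    names(sets) <- rownames(tpi)
    return(sets)
  }
  detect_epicenters_row(tpi, "subject", z_threshold)
}

detect_epicenters_row <- function(x, id, z_threshold) {
  if (length(x) < 3) stop("need at least 3 retained regions", call. = FALSE)
  if (any(!is.finite(x))) stop("TPI values must be finite", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    warning(sprintf("subject %s has constant TPI; no epicenters defined", id))
    z <- rep(NA_real_, length(x)); names(z) <- names(x)
    return(structure(list(subject = id, regions = character(0), zscores = z,
                          threshold = z_threshold, degenerate = TRUE),
                     class = "epicenter_set"))
  }
  z <- (x - mean(x)) / s
  structure(list(subject = id, regions = names(x)[z >= z_threshold],
                 zscores = z, threshold = z_threshold, degenerate = FALSE),
            class = "epicenter_set")
}

#' @export
print.epicenter_set <- function(x, ...) {
  cat(sprintf("Epicenter set for %s (z >= %.3f): %s\n", x$subject, x$threshold,
              if (length(x$regions) == 0) "<none>"
              else paste(x$regions, collapse = ", ")))
  invisible(x)
}

#' Canonical group epicenters (bilateral entorhinal cortex)
#'
#' @param labels retained region labels the canonical set must be drawn from.
#' @param erc_labels the two entorhinal labels (default `L_ERC`, `R_ERC`).
#' @return an `epicenter_set` with subject id `"canonical"`.
#' @export
canonical_epicenters <- function(labels, erc_labels = c("L_ERC", "R_ERC")) {
  missing_l <- setdiff(erc_labels, labels)
  if (length(missing_l) > 0)
    stop("canonical epicenter label(s) not among retained regions: ",
         paste(missing_l, collapse = ", "), call. = FALSE)
  structure(list(subject = "canonical", regions = erc_labels,
                 zscores = NULL, threshold = NA_real_, degenerate = FALSE),
            class = "epicenter_set")
}

#' Epicenter frequency across subjects, with between-fold agreement
#'
#' Computes, for each region, the proportion of subjects (among those with at
#' least one epicenter) whose set contains the region. When fold labels are
#' supplied, per-fold frequency vectors are compared by ICC(2,1): pairwise
#' between folds and between each fold and the pooled vector.
#'
#' @param sets list of `epicenter_set` objects.
#' @param regions region labels defining the table (default: union of members).
#' @param folds optional vector of fold labels, one per set.
#' @return list with `proportion` (named vector), `n_subjects` (denominator),
#'   and, when folds are given, `fold_proportion` (regions x folds),
#'   `icc_pairwise` (matrix), `icc_vs_pooled` (vector).
#' @export
epicenter_frequency <- function(sets, regions = NULL, folds = NULL) {
  nonempty <- vapply(sets, function(s) length(s$regions) > 0, logical(1))
  if (!any(nonempty)) stop("no non-empty epicenter sets", call. = FALSE)
  if (is.null(regions))
    regions <- sort(unique(unlist(lapply(sets, `[[`, "regions"))))
  member <- vapply(sets, function(s) regions %in% s$regions,
                   logical(length(regions)))
  member <- matrix(member, nrow = length(regions),
                   dimnames = list(regions, names(sets)))
  denom <- sum(nonempty)
  prop <- rowSums(member[, nonempty, drop = FALSE]) / denom
  out <- list(proportion = prop, n_subjects = denom)
  if (!is.null(folds)) {
    stopifnot(length(folds) == length(sets))
    fl <- sort(unique(folds))
    fp <- vapply(fl, function(f) {
      idx <- folds == f & nonempty
      rowSums(member[, idx, drop = FALSE]) / max(sum(idx), 1)
    }, numeric(length(regions)))
    colnames(fp) <- as.character(fl)
    icc_pw <- matrix(NA_real_, length(fl), length(fl),
                     dimnames = list(fl, fl))
    for (i in seq_along(fl)) for (j in seq_along(fl)) {
      if (i < j) {
        v <- icc_2_1(cbind(fp[, i], fp[, j]))$icc
        icc_pw[i, j] <- icc_pw[j, i] <- v
      }
    }
    diag(icc_pw) <- 1
    icc_pool <- vapply(seq_along(fl), function(i)
      icc_2_1(cbind(fp[, i], prop))$icc, numeric(1))
    names(icc_pool) <- as.character(fl)
    out$fold_proportion <- fp
    out$icc_pairwise <- icc_pw
    out$icc_vs_pooled <- icc_pool
  }
  out
}
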