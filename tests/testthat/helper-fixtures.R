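# Shared fixtures (memoized so expensive cohorts are built once per run)
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# compact cohort for structural/shape tests
small_config <- function(...) {
  cohort_config(n_subjects = 60, n_regions = 40, n_nonspecific_regions = 12,
                seed = 101L, ...)
}

small_cohort <- function() {
  memo("small_cohort", generate_cohort(small_config(), seed = 101L))
}

small_stages <- function() {
  memo("small_stages", {
    cohort <- small_cohort()
    models <- suppressWarnings(fit_region_mixtures(cohort$suvr, n_restarts = 1))
    tpi <- build_tpi_table(cohort$suvr, models)
    eps <- suppressWarnings(detect_epicenters(tpi))
    retained <- retained_regions(models)
    canonical <- canonical_epicenters(retained)
    grp <- group_connectome(cohort$connectomes$subjects, cohort$metadata)
    profiles <- suppressWarnings(epicenter_distance_profiles(
      cohort$connectomes$subjects, eps, canonical, grp, retained))
    list(cohort = cohort, models = models, tpi = tpi, eps = eps,
         retained = retained, canonical = canonical, group = grp,
         profiles = profiles)
  })
}

# full-size cohort (default parcellation) for recovery tests
medium_cohort <- function() {
  memo("medium_cohort",
       generate_cohort(cohort_config(n_subjects = 150, seed = 202L),
                       seed = 202L))
}

medium_stages <- function() {
  memo("medium_stages", {
    cohort <- medium_cohort()
    models <- suppressWarnings(fit_region_mixtures(cohort$suvr, n_restarts = 1))
    tpi <- build_tpi_table(cohort$suvr, models)
    eps <- suppressWarnings(detect_epicenters(tpi))
    retained <- retained_regions(models)
    canonical <- canonical_epicenters(retained)
    grp <- group_connectome(cohort$connectomes$subjects, cohort$metadata)
    profiles <- suppressWarnings(epicenter_distance_profiles(
      cohort$connectomes$subjects, eps, canonical, grp, retained))
    list(cohort = cohort, models = models, tpi = tpi, eps = eps,
         retained = retained, canonical = canonical, group = grp,
         profiles = profiles)
  })
}

# independent Floyd-Warshall oracle on reciprocal-weight costs
fw_distances <- function(w) {
  n <- nrow(w)
  D <- matrix(Inf, n, n)
  D[w > 0] <- 1 / w[w > 0]
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) {
    through <- D[i, k] + D[k, ]
    lower <- through < D[i, ]
    D[i, lower] <- through[lower]
  }
  dimnames(D) <- dimnames(w)
  D
}

# random symmetric weight matrix in [0, 1] with zero diagonal
random_weights <- function(n, density = 1, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- stats::runif(sum(ut))^2
  if (density < 1) vals[stats::runif(sum(ut)) > density] <- 0
  w[ut] <- vals
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  rownames(w) <- colnames(w) <- sprintf("R%02d", seq_len(n))
  w
}
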