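#' Configuration for the synthetic tau-spread cohort generator
#'
#' Builds the full parameter set for [generate_cohort()]. Defaults emulate the
#' data structure the analysis pipeline assumes: a 104-region parcellation of
#' which 40 regions show only non-specific tracer binding (unimodal SUVR) and
#' 64 show a two-component Gaussian mixture; dense, heavy-tailed structural
#' connectivity weights in \[0, 1\]; subject-specific tau epicenters drawn from
#' a medial-temporal-weighted pool; pathologic-component occupancy that decays
#' with connectivity distance from the epicenters; amyloid-status severity
#' differences; small covariate effects; and distance-graded longitudinal
#' accumulation.
#'
#' @param n_subjects number of participants.
#' @param n_regions number of parcellation regions (graph nodes).
#' @param n_nonspecific_regions number of regions generated with a unimodal
#'   (non-specific-binding) SUVR distribution; must be `< n_regions`.
#' @param positivity fraction of amyloid-positive participants; the generator
#'   assigns exactly `round(positivity * n_subjects)` positives.
#' @param weight_law parameters of the edge-weight law: log-weights are
#'   `mu0 - d/lambda + N(0, sigma)` for latent 3-D inter-node distance `d`,
#'   exponentiated and clipped to \[0, 1\]; weights below `floor` become
#'   non-edges.
#' @param subject_noise_sd log-scale SD of the multiplicative noise that
#'   perturbs the template connectome into each subject's connectome.
#' @param epicenter_count_range integer range (inclusive) of the per-subject
#'   epicenter count, drawn uniformly.
#' @param epicenter_pool_weight sampling weight of the limbic pool regions
#'   relative to other mixture regions when drawing epicenters.
#' @param epicenter_quantiles range of pathologic-component quantiles that a
#'   subject's own epicenter regions draw from (always pathologic, upper
#'   tail of the same component), making them that subject's relative
#'   outliers without distorting the pooled per-region mixture.
#' @param subthreshold_gradient amplitude (SUVR) of the continuous
#'   distance-graded mean shift `gradient * severity * plogis(a - b * dbar_r)`
#'   added to every mixture-region draw, modeling sub-threshold tau that
#'   accumulates with connectome proximity even below mixture-component
#'   resolution.
#' @param distance_effect named vector `c(a, b, floor)` of the occupancy
#'   link: the probability that a subject draws region `r` from the
#'   pathologic component is
#'   `min(1, floor + severity * plogis(a - b * dbar_r))` where `dbar_r` is
#'   the mean shortest-path distance of `r` from the subject's epicenters;
#'   `b >= 0`. The small distance-independent `floor` models off-pathway
#'   pathology and keeps every mixture region bimodal at the cohort level.
#' @param severity_range list with elements `abneg` and `abpos`, each a
#'   `c(min, max)` range for the uniform severity draw by amyloid status.
#' @param covariate_effects list of linear effects added to SUVR: `age` (per
#'   year, centered at 71), `sex_M`, `education` (per year, centered at 16),
#'   `race` (named vector of offsets vs. White), `study_ADNI`, and `interval`
#'   (per year between PET and dMRI).
#' @param longitudinal list controlling follow-up generation: `c0`, `c1`,
#'   `noise_sd` of the annualized SUVR change `c0 - c1 * dbar_r + noise` in
#'   mixture regions; `mean_interval`/`sd_interval` (years) of the inter-scan
#'   interval; `fraction` of amyloid-positive subjects given a follow-up scan.
#' @param connectome_threshold fraction of weakest positive edges removed when
#'   a connectome is prepared for network analysis.
#' @param mixture_truth optional data frame overriding the per-region
#'   generative distributions; see [default_mixture_truth()].
#' @param seed default RNG seed used by the generators.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 233,
                          n_regions = 104,
                          n_nonspecific_regions = 40,
                          positivity = 0.36,
                          weight_law = list(mu0 = log(0.10), lambda = 0.75,
                                            sigma = 1.0, floor = 1e-4),
                          subject_noise_sd = 0.6,
                          epicenter_count_range = c(1L, 7L),
                          epicenter_pool_weight = 10,
                          epicenter_quantiles = c(0.97, 0.998),
                          subthreshold_gradient = 0.06,
                          distance_effect = c(a = 5, b = 1.2, floor = 0.03),
                          severity_range = list(abneg = c(0.05, 0.25),
                                                abpos = c(0.25, 0.65)),
                          covariate_effects = list(
                            age = 0.002, sex_M = 0.02, education = -0.002,
                            race = c(Black = 0.01, Asian = 0.01, Multiple = 0.01),
                            study_ADNI = 0.015, interval = 0.01),
                          longitudinal = list(c0 = 0.018, c1 = 0.002,
                                              noise_sd = 0.003,
                                              mean_interval = 3.18,
                                              sd_interval = 1.35,
                                              fraction = 0.6),
                          connectome_threshold = 0.10,
                          mixture_truth = NULL,
                          seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_regions) || n_regions < 4)
    stop("`n_regions` must be a positive integer >= 4", call. = FALSE)
  if (n_nonspecific_regions < 0 || n_nonspecific_regions >= n_regions)
    stop("`n_nonspecific_regions` must be in [0, n_regions)", call. = FALSE)
  if (subject_noise_sd < 0)
    stop("`subject_noise_sd` must be >= 0", call. = FALSE)
  if (distance_effect[["b"]] < 0)
    stop("distance effect slope `b` must be >= 0", call. = FALSE)
  if (positivity < 0 || positivity > 1)
    stop("`positivity` must be in [0, 1]", call. = FALSE)
  if (connectome_threshold < 0 || connectome_threshold >= 1)
    stop("`connectome_threshold` must be in [0, 1)", call. = FALSE)

  labels <- region_labels(n_regions, n_nonspecific_regions)
  if (is.null(mixture_truth))
    mixture_truth <- default_mixture_truth(labels)
  with(mixture_truth[!mixture_truth$unimodal, ], {
    if (any(mu_p <= mu_n)) stop("mixture truth requires mu_p > mu_n", call. = FALSE)
  })
  if (sum(mixture_truth$unimodal) != n_nonspecific_regions)
    stop("unimodal flag count must equal n_nonspecific_regions", call. = FALSE)

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_regions = as.integer(n_regions),
    n_nonspecific_regions = as.integer(n_nonspecific_regions),
    positivity = positivity,
    weight_law = weight_law,
    subject_noise_sd = subject_noise_sd,
    epicenter_count_range = as.integer(epicenter_count_range),
    epicenter_pool_weight = epicenter_pool_weight,
    epicenter_quantiles = epicenter_quantiles,
    subthreshold_gradient = subthreshold_gradient,
    distance_effect = distance_effect,
    severity_range = severity_range,
    covariate_effects = covariate_effects,
    longitudinal = longitudinal,
    connectome_threshold = connectome_threshold,
    labels = labels,
    mixture_truth = mixture_truth,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Region labels for the synthetic parcellation
#'
#' Regions come in bilateral pairs. The first eight are a "limbic" pool
#' (entorhinal cortex, amygdala, hippocampus, parahippocampal gyrus) that is
#' over-weighted when epicenters are sampled; the last
#' `n_nonspecific` regions (subcortical-like labels) are generated unimodal.
#'
#' @param n_regions total region count (even).
#' @param n_nonspecific number of unimodal regions (even).
#' @return character vector of region labels; the unimodal block carries the
#'   attribute `"unimodal"` (logical vector) and the limbic pool the attribute
#'   `"limbic"`.
#' @export
region_labels <- function(n_regions, n_nonspecific) {
  limbic <- c("L_ERC", "R_ERC", "L_Amygdala", "R_Amygdala",
              "L_Hippocampus", "R_Hippocampus",
              "L_Parahippocampal", "R_Parahippocampal")
  limbic <- limbic[seq_len(min(8L, n_regions - n_nonspecific))]
  n_mix_extra <- n_regions - n_nonspecific - length(limbic)
  ctx <- character(0)
  if (n_mix_extra > 0) {
    pairs <- ceiling(n_mix_extra / 2)
    ctx <- as.vector(rbind(sprintf("L_Ctx%02d", seq_len(pairs)),
                           sprintf("R_Ctx%02d", seq_len(pairs))))[seq_len(n_mix_extra)]
  }
  sub <- character(0)
  if (n_nonspecific > 0) {
    pairs <- ceiling(n_nonspecific / 2)
    sub <- as.vector(rbind(sprintf("L_Sub%02d", seq_len(pairs)),
                           sprintf("R_Sub%02d", seq_len(pairs))))[seq_len(n_nonspecific)]
  }
  labels <- c(limbic, ctx, sub)
  attr(labels, "unimodal") <- c(rep(FALSE, length(limbic) + length(ctx)),
                                rep(TRUE, length(sub)))
  attr(labels, "limbic") <- c(rep(TRUE, length(limbic)),
                              rep(FALSE, length(ctx) + length(sub)))
  labels
}

#' Default per-region generative SUVR distributions
#'
#' Mixture regions get a non-pathologic component centered near 1 (SUVR is
#' referenced to cerebellum) and a well-separated pathologic component
#' (separation about 4.8 pooled SDs); unimodal regions get a single Gaussian.
#' Means vary deterministically across regions so no two regions are identical.
#'
#' @param labels output of [region_labels()].
#' @return data frame with columns `region`, `unimodal`, `mu_n`, `sigma_n`,
#'   `mu_p`, `sigma_p` (the latter two `NA` for unimodal regions).
#' @export
default_mixture_truth <- function(labels) {
  unimodal <- attr(labels, "unimodal")
  n <- length(labels)
  spread <- seq(0, 1, length.out = n)
  mu_n <- ifelse(unimodal, 1.00 + 0.25 * spread, 0.95 + 0.20 * spread)
  sigma_n <- ifelse(unimodal, 0.10, 0.08)
  data.frame(region = as.character(labels),
             unimodal = unimodal,
             mu_n = mu_n, sigma_n = sigma_n,
             mu_p = ifelse(unimodal, NA_real_, mu_n + 0.55),
             sigma_p = ifelse(unimodal, NA_real_, 0.15),
             stringsAsFactors = FALSE)
}

#' Generate a template connectome and per-subject perturbations
#'
#' The template places regions uniformly in a latent 3-D cube and assigns
#' log-normal edge weights with exponential spatial decay, clipped to
#' \[0, 1\] — a dense, heavy-tailed weight distribution of the kind produced by
#' normalized probabilistic tractography. Each subject's connectome is the
#' template perturbed edge-wise by multiplicative log-normal noise and
#' re-clipped, so the edge set (zero pattern) is shared across subjects.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `template` (matrix), `subjects` (list of matrices, one per
#'   subject), and `labels`.
#' @export
generate_connectomes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_regions
  wl <- config$weight_law
  pos <- matrix(stats::runif(n * 3), n, 3)
  d <- as.matrix(stats::dist(pos))
  noise <- matrix(0, n, n)
  ut <- upper.tri(noise)
  noise[ut] <- stats::rnorm(sum(ut), 0, wl$sigma)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  w <- exp(wl$mu0 - d / wl$lambda + noise)
  w <- pmin(w, 1)
  w[w < wl$floor] <- 0
  diag(w) <- 0
  dimnames(w) <- list(as.character(config$labels), as.character(config$labels))

  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    if (config$subject_noise_sd == 0) {
      subjects[[s]] <- w
    } else {
      pert <- matrix(0, n, n)
      pert[ut] <- stats::rnorm(sum(ut), 0, config$subject_noise_sd)
      pert[lower.tri(pert)] <- t(pert)[lower.tri(pert)]
      ws <- pmin(w * exp(pert), 1)
      diag(ws) <- 0
      dimnames(ws) <- dimnames(w)
      subjects[[s]] <- ws
    }
  }
  names(subjects) <- sprintf("sub-%03d", seq_len(config$n_subjects))
  list(template = w, subjects = subjects, labels = as.character(config$labels))
}

#' Sample the cohort ground truth and participant metadata
#'
#' Assigns exactly `round(positivity * n)` amyloid-positive participants,
#' draws per-subject severity from the status-specific range, samples 1-7
#' epicenters per subject from the mixture regions with the limbic pool
#' over-weighted, and generates demographic covariates (age, sex, education,
#' race, study, PET-dMRI interval) and a clinical diagnosis whose distribution
#' depends on amyloid status.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @return list with `metadata` (data frame, one row per subject) and `truth`
#'   (list: `epicenters` — list of region-label vectors, `severity`,
#'   `unimodal` flags, `distance_effect`).
#' @export
sample_ground_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_subjects
  ids <- sprintf("sub-%03d", seq_len(n))

  n_pos <- round(config$positivity * n)
  abeta <- rep(FALSE, n)
  abeta[sample.int(n, n_pos)] <- TRUE

  sev <- numeric(n)
  rng <- config$severity_range
  sev[abeta] <- stats::runif(sum(abeta), rng$abpos[1], rng$abpos[2])
  sev[!abeta] <- stats::runif(sum(!abeta), rng$abneg[1], rng$abneg[2])

  # diagnosis mix conditioned on amyloid status (CU-dominant in negatives)
  dx_levels <- c("CU", "MCI", "Dementia")
  dx <- character(n)
  dx[abeta] <- sample(dx_levels, sum(abeta), replace = TRUE,
                      prob = c(0.44, 0.46, 0.10))
  dx[!abeta] <- sample(dx_levels, sum(!abeta), replace = TRUE,
                       prob = c(0.83, 0.16, 0.01))

  metadata <- data.frame(
    subject_id = ids,
    age = round(pmin(pmax(stats::rnorm(n, 71, 7), 50), 90), 1),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4)),
    education = round(pmin(pmax(stats::rnorm(n, 16, 2.5), 9), 20)),
    race = sample(c("White", "Black", "Asian", "Multiple"), n, replace = TRUE,
                  prob = c(0.79, 0.19, 0.01, 0.01)),
    study = sample(c("ABC", "ADNI"), n, replace = TRUE, prob = c(0.35, 0.65)),
    scan_interval = round(stats::runif(n, 0, 1.5), 2),
    diagnosis = dx,
    abeta_positive = abeta,
    stringsAsFactors = FALSE
  )

  mixture_regions <- config$labels[!attr(config$labels, "unimodal")]
  pool_w <- ifelse(attr(config$labels, "limbic")[!attr(config$labels, "unimodal")],
                   config$epicenter_pool_weight, 1)
  k_rng <- config$epicenter_count_range
  epicenters <- lapply(seq_len(n), function(s) {
    k <- sample(seq(k_rng[1], k_rng[2]), 1)
    sample(mixture_regions, k, prob = pool_w)
  })
  names(epicenters) <- ids

  list(metadata = metadata,
       truth = list(epicenters = epicenters,
                    severity = stats::setNames(sev, ids),
                    unimodal = stats::setNames(attr(config$labels, "unimodal"),
                                               as.character(config$labels)),
                    distance_effect = config$distance_effect))
}

# Mean shortest-path distance of every region from each subject's epicenters,
# computed on the full (unthresholded) subject graphs. Subject graphs share
# the template's edge set, so one igraph skeleton serves all subjects.
cohort_distance_profiles <- function(connectomes, epicenters) {
  template <- connectomes$template
  labels <- connectomes$labels
  g <- igraph::graph_from_adjacency_matrix(template > 0, mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  idx <- cbind(el[, 1], el[, 2])
  n_sub <- length(connectomes$subjects)
  dbar <- matrix(NA_real_, n_sub, length(labels),
                 dimnames = list(names(connectomes$subjects), labels))
  for (s in seq_len(n_sub)) {
    w <- connectomes$subjects[[s]][idx]
    eps <- match(epicenters[[s]], labels)
    D <- igraph::distances(g, v = eps, weights = 1 / w)
    dbar[s, ] <- colMeans(D)
  }
  dbar
}

#' Generate baseline regional SUVR for a synthetic cohort
#'
#' Unimodal regions draw from their single Gaussian for every subject. In
#' mixture regions, each subject draws from the pathologic component with
#' probability `min(1, floor + severity * plogis(a - b * dbar_r))` (their own
#' epicenter regions always draw from the upper quantiles of the pathologic
#' component), otherwise from the non-pathologic component; a small
#' severity-scaled distance-graded mean shift models sub-threshold tau. Covariate effects are added linearly and values
#' are floored just above zero.
#'
#' @param config a [cohort_config()].
#' @param connectomes output of [generate_connectomes()].
#' @param truth the `truth` element of [sample_ground_truth()].
#' @param metadata the `metadata` element of [sample_ground_truth()].
#' @param seed RNG seed.
#' @param dbar optional precomputed subject-by-region distance matrix.
#' @return numeric matrix (subjects by regions) of SUVR with attributes
#'   `pathologic` (logical draw indicator matrix) and `dbar`.
#' @export
generate_regional_suvr <- function(config, connectomes, truth, metadata,
                                   seed = config$seed, dbar = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(lengths(truth$epicenters) == 0))
    stop("every subject must have at least one epicenter", call. = FALSE)
  if (is.null(dbar))
    dbar <- cohort_distance_profiles(connectomes, truth$epicenters)
  set.seed(seed)
  labels <- as.character(config$labels)
  mt <- config$mixture_truth
  n <- config$n_subjects
  ids <- metadata$subject_id
  a <- config$distance_effect[["a"]]
  b <- config$distance_effect[["b"]]
  p_floor <- if ("floor" %in% names(config$distance_effect))
    config$distance_effect[["floor"]] else 0

  ce <- config$covariate_effects
  offset <- ce$age * (metadata$age - 71) +
    ce$sex_M * (metadata$sex == "M") +
    ce$education * (metadata$education - 16) +
    ifelse(metadata$race %in% names(ce$race), ce$race[metadata$race], 0) +
    ce$study_ADNI * (metadata$study == "ADNI") +
    ce$interval * metadata$scan_interval

  suvr <- matrix(NA_real_, n, length(labels), dimnames = list(ids, labels))
  patho <- matrix(FALSE, n, length(labels), dimnames = list(ids, labels))
  sev <- truth$severity[ids]
  for (j in seq_along(labels)) {
    row <- mt[j, ]
    if (row$unimodal) {
      suvr[, j] <- stats::rnorm(n, row$mu_n, row$sigma_n)
    } else {
      prox <- stats::plogis(a - b * dbar[, j])
      p <- pmin(1, p_floor + sev * prox)
      is_ep <- vapply(truth$epicenters[ids], function(e) labels[j] %in% e, logical(1))
      draw <- stats::runif(n) < p
      draw[is_ep] <- TRUE
      grad <- config$subthreshold_gradient * sev * prox
      mu <- ifelse(draw, row$mu_p, row$mu_n) + grad
      sg <- ifelse(draw, row$sigma_p, row$sigma_n)
      x <- stats::rnorm(n, mu, sg)
      # epicenter regions draw from the upper tail of their own pathologic
      # component, so they are within-subject outliers but the pooled
      # per-region distribution stays inside the component's support
      if (any(is_ep)) {
        u <- stats::runif(sum(is_ep), config$epicenter_quantiles[1],
                          config$epicenter_quantiles[2])
        x[is_ep] <- stats::qnorm(u, row$mu_p, row$sigma_p) + grad[is_ep]
      }
      suvr[, j] <- x
      patho[, j] <- draw
    }
  }
  suvr <- suvr + offset
  suvr <- pmax(suvr, 1e-3)
  attr(suvr, "pathologic") <- patho
  attr(suvr, "dbar") <- dbar
  suvr
}

#' Generate follow-up SUVR for a longitudinal subset
#'
#' A fraction of amyloid-positive subjects receives a follow-up scan after a
#' positive inter-scan interval (Gaussian, resampled until > 0.25 years).
#' Tau accumulation is imposed on the tau-pathology-index scale: in mixture
#' regions the annualized TPI change is `c0 - c1 * dbar_r` plus Gaussian
#' noise — accumulation is fastest in regions closest to the subject's
#' epicenters — and the drifted TPI (clipped inside (-1, 1)) is mapped back
#' to SUVR through the inverse of the region's true two-component transform.
#' Unimodal regions receive only small measurement noise.
#'
#' @param baseline output of [generate_regional_suvr()].
#' @param truth,metadata outputs of [sample_ground_truth()].
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @return list with `followup` (SUVR matrix for the subset), `intervals`
#'   (named vector, years) and `rate_truth` (matrix of expected annualized
#'   TPI change, before noise and clipping).
#' @export
generate_longitudinal <- function(baseline, truth, metadata, config,
                                  seed = config$seed) {
  set.seed(seed)
  lg <- config$longitudinal
  pos_ids <- metadata$subject_id[metadata$abeta_positive]
  n_long <- max(1L, round(lg$fraction * length(pos_ids)))
  ids <- sort(sample(pos_ids, n_long))

  intervals <- vapply(ids, function(i) {
    it <- -1
    while (it <= 0.25) it <- stats::rnorm(1, lg$mean_interval, lg$sd_interval)
    it
  }, numeric(1))

  dbar <- attr(baseline, "dbar")[ids, , drop = FALSE]
  mt <- config$mixture_truth
  unimodal <- truth$unimodal[colnames(baseline)]
  rate <- sweep(-lg$c1 * dbar, 1, lg$c0, "+")
  rate[, unimodal] <- 0

  followup <- baseline[ids, , drop = FALSE]
  for (j in seq_len(ncol(followup))) {
    if (unimodal[j]) {
      followup[, j] <- followup[, j] + stats::rnorm(length(ids), 0, 0.01)
      next
    }
    row <- mt[j, ]
    true_tpi <- function(x)
      stats::pnorm(x, row$mu_p, row$sigma_p) +
        stats::pnorm(x, row$mu_n, row$sigma_n) - 1
    t0 <- true_tpi(followup[, j])
    t1 <- t0 + (rate[, j] + stats::rnorm(length(ids), 0, lg$noise_sd)) *
      intervals
    t1 <- pmin(pmax(t1, -1 + 1e-9), 1 - 1e-9)
    # invert the monotone TPI transform on a fine grid
    grid <- seq(row$mu_n - 8 * row$sigma_n, row$mu_p + 8 * row$sigma_p,
                length.out = 4001)
    followup[, j] <- stats::approx(true_tpi(grid), grid, xout = t1,
                                   rule = 2, ties = "ordered")$y
  }
  followup <- pmax(followup, 1e-3)
  list(followup = followup, intervals = intervals, rate_truth = rate)
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates [generate_connectomes()], [sample_ground_truth()],
#' [generate_regional_suvr()] and [generate_longitudinal()] under a single
#' master seed (per-stage seeds are derived deterministically), and optionally
#' writes all artifacts to disk in plain-text formats.
#'
#' @param config a [cohort_config()].
#' @param seed master RNG seed (defaults to `config$seed`).
#' @param longitudinal generate a follow-up subset? (default `TRUE`)
#' @param write_dir optional directory; when given, writes per-subject
#'   adjacency TSVs, `suvr_baseline.csv` / `suvr_followup.csv` (long format),
#'   `metadata.csv`, and `ground_truth.json`.
#' @return object of class `tau_cohort`: list with `config`, `connectomes`,
#'   `suvr`, `metadata`, `truth`, and `longitudinal`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed,
                            longitudinal = TRUE, write_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  connectomes <- generate_connectomes(config, seed = stage_seeds[1])
  gt <- sample_ground_truth(config, seed = stage_seeds[2])
  suvr <- generate_regional_suvr(config, connectomes, gt$truth, gt$metadata,
                                 seed = stage_seeds[3])
  long <- NULL
  if (longitudinal && any(gt$metadata$abeta_positive))
    long <- generate_longitudinal(suvr, gt$truth, gt$metadata, config,
                                  seed = stage_seeds[4])

  cohort <- structure(list(config = config, connectomes = connectomes,
                           suvr = suvr, metadata = gt$metadata,
                           truth = gt$truth, longitudinal = long,
                           seed = seed),
                      class = "tau_cohort")
  if (!is.null(write_dir)) write_cohort(cohort, write_dir)
  cohort
}

#' @export
print.tau_cohort <- function(x, ...) {
  cat("Synthetic tau-spread cohort\n")
  cat(sprintf("  %d subjects, %d regions (%d non-specific)\n",
              x$config$n_subjects, x$config$n_regions,
              x$config$n_nonspecific_regions))
  cat(sprintf("  amyloid-positive: %d; longitudinal subset: %d\n",
              sum(x$metadata$abeta_positive),
              if (is.null(x$longitudinal)) 0L else nrow(x$longitudinal$followup)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' @param cohort a `tau_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$connectomes$subjects))
    write_connectome_tsv(cohort$connectomes$subjects[[id]],
                         file.path(dir, paste0(id, "_connectome.tsv")))
  write_connectome_tsv(cohort$connectomes$template,
                       file.path(dir, "template_connectome.tsv"))
  utils::write.csv(regional_to_long(cohort$suvr),
                   file.path(dir, "suvr_baseline.csv"), row.names = FALSE)
  if (!is.null(cohort$longitudinal)) {
    utils::write.csv(regional_to_long(cohort$longitudinal$followup),
                     file.path(dir, "suvr_followup.csv"), row.names = FALSE)
    utils::write.csv(data.frame(subject_id = names(cohort$longitudinal$intervals),
                                interval_years = unname(cohort$longitudinal$intervals)),
                     file.path(dir, "intervals.csv"), row.names = FALSE)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  gt <- list(epicenters = cohort$truth$epicenters,
             severity = as.list(cohort$truth$severity),
             unimodal = names(which(cohort$truth$unimodal)),
             distance_effect = as.list(cohort$truth$distance_effect),
             seed = cohort$seed)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Convert a subjects-by-regions matrix to long format
#' @param x matrix with subject row names and region column names.
#' @return data frame with columns `subject_id`, `region`, `value`.
#' @export
regional_to_long <- function(x) {
  data.frame(subject_id = rep(rownames(x), times = ncol(x)),
             region = rep(colnames(x), each = nrow(x)),
             value = as.vector(x), stringsAsFactors = FALSE)
}

#' Convert a long-format regional table to a subjects-by-regions matrix
#' @param df data frame with columns `subject_id`, `region`, `value`.
#' @return numeric matrix.
#' @export
regional_to_wide <- function(df) {
  stopifnot(all(c("subject_id", "region", "value") %in% names(df)))
  subjects <- unique(df$subject_id)
  regions <- unique(df$region)
  m <- matrix(NA_real_, length(subjects), length(regions),
              dimnames = list(subjects, regions))
  m[cbind(match(df$subject_id, subjects), match(df$region, regions))] <- df$value
  m
}
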