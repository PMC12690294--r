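#' Run the full individualized tau-spread pipeline
#'
#' Orchestrates every stage end to end on a cohort: per-region
#' Gaussian-mixture fits and region exclusion, TPI conversion, individualized
#' and canonical epicenters, individual and group connectome distance
#' profiles, the four-variant cross-validated group models, subject-level
#' effect sizes, and (when follow-up scans are present) the longitudinal
#' models. Optionally writes all result tables as CSV plus a JSON run
#' manifest.
#'
#' @param cohort a `tau_cohort` from [generate_cohort()], or an equivalent
#'   list with elements `connectomes` (`$subjects`, named list of raw
#'   adjacency matrices), `suvr`, `metadata`, and optionally `longitudinal`
#'   (`$followup`, `$intervals`).
#' @param z_threshold epicenter z-score threshold.
#' @param connectome_threshold fraction of weakest edges excluded.
#' @param k folds for cross-validation.
#' @param seed seed for the fold assignment.
#' @param residualize covariate-adjustment method (`"lmm"`, `"ols"`, `"none"`).
#' @param out_dir optional output directory for result CSVs and the manifest.
#' @return list with `models` (`region_mixtures`), `tpi`, `epicenters`,
#'   `profiles`, `fit` (`tau_spread`), `subject` (subject-level effects),
#'   `longitudinal` (`tau_spread_long` or `NULL`), `frequency`.
#' @export
run_pipeline <- function(cohort, z_threshold = 1.645,
                         connectome_threshold = 0.10, k = 5, seed = 17L,
                         residualize = "lmm", out_dir = NULL) {
  suvr <- cohort$suvr
  metadata <- cohort$metadata

  models <- fit_region_mixtures(suvr)
  tpi <- build_tpi_table(suvr, models)
  retained <- retained_regions(models)
  if (!all(c("L_ERC", "R_ERC") %in% retained))
    stop("pipeline aborted at epicenter stage: canonical region not retained",
         call. = FALSE)

  eps <- detect_epicenters(tpi, z_threshold = z_threshold)
  canonical <- canonical_epicenters(retained)

  missing_conn <- setdiff(rownames(suvr), names(cohort$connectomes$subjects))
  if (length(missing_conn) > 0)
    stop("pipeline aborted at distance stage: no connectome for subject ",
         missing_conn[1], call. = FALSE)

  group <- group_connectome(cohort$connectomes$subjects, metadata,
                            exclude_bottom_fraction = connectome_threshold)
  profiles <- epicenter_distance_profiles(
    cohort$connectomes$subjects, eps, canonical, group, retained,
    exclude_bottom_fraction = connectome_threshold)

  fit <- fit_tau_spread(tpi, profiles, metadata, eps, k = k, seed = seed,
                        residualize = residualize)

  abpos_ids <- intersect(fit$included,
                         metadata$subject_id[metadata$abeta_positive])
  subject <- subject_level_analysis(fit, tpi, profiles, subjects = abpos_ids)

  longitudinal <- NULL
  if (!is.null(cohort$longitudinal)) {
    fu_suvr <- cohort$longitudinal$followup
    fu_tpi <- build_tpi_table(fu_suvr, models)
    ann <- annualize_change(tpi, fu_tpi, cohort$longitudinal$intervals)
    long_ids <- intersect(rownames(fu_tpi), fit$included)
    ann$annualized <- ann$annualized[long_ids, , drop = FALSE]
    longitudinal <- longitudinal_analysis(tpi, ann, profiles)
  }

  frequency <- epicenter_frequency(eps[fit$included], regions = retained,
                                   folds = fit$folds[fit$included])

  out <- list(models = models, tpi = tpi, epicenters = eps,
              profiles = profiles, fit = fit, subject = subject,
              longitudinal = longitudinal, frequency = frequency,
              settings = list(z_threshold = z_threshold,
                              connectome_threshold = connectome_threshold,
                              k = k, seed = seed, residualize = residualize))
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$models$summary, file.path(dir, "region_models.csv"),
                   row.names = FALSE)
  utils::write.csv(regional_to_long(out$tpi), file.path(dir, "tpi.csv"),
                   row.names = FALSE)
  utils::write.csv(out$fit$results, file.path(dir, "group_models.csv"),
                   row.names = FALSE)
  utils::write.csv(out$fit$interaction,
                   file.path(dir, "interaction.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = rownames(out$subject$effects),
                              out$subject$effects, check.names = FALSE),
                   file.path(dir, "subject_effects.csv"), row.names = FALSE)
  utils::write.csv(data.frame(region = names(out$frequency$proportion),
                              proportion = unname(out$frequency$proportion)),
                   file.path(dir, "epicenter_frequency.csv"), row.names = FALSE)
  if (!is.null(out$longitudinal)) {
    lg <- out$longitudinal
    gtab <- do.call(rbind, lapply(names(lg$group), function(v)
      data.frame(variant = v, beta_std = lg$group[[v]]$beta_std,
                 ci_lo = lg$group[[v]]$ci[1], ci_hi = lg$group[[v]]$ci[2],
                 t = lg$group[[v]]$t, p = lg$group[[v]]$p,
                 r2 = lg$group[[v]]$r2, stringsAsFactors = FALSE)))
    utils::write.csv(gtab, file.path(dir, "longitudinal_models.csv"),
                     row.names = FALSE)
    utils::write.csv(lg$comparisons,
                     file.path(dir, "longitudinal_comparisons.csv"),
                     row.names = FALSE)
  }
  eps_json <- lapply(out$epicenters, function(s)
    list(regions = s$regions, zscores = as.list(s$zscores),
         threshold = s$threshold))
  jsonlite::write_json(eps_json, file.path(dir, "epicenters.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(settings = out$settings,
                   n_subjects = nrow(out$tpi),
                   n_retained = ncol(out$tpi),
                   package_version = as.character(utils::packageVersion("tauspread")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
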