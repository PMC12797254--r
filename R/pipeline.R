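# End-to-end pipeline: simulate -> QC -> first level -> conjunction ->
# naive RSA -> cross-validated RSA, with deterministic seeding and
# provenance.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Thresholds default to the
#' protocol's values: voxelwise p < 0.001 for both contrasts, cluster-level
#' alpha 0.05, family alpha 0.05. The config round-trips losslessly through
#' JSON ([write_config()] / [read_config()]).
#'
#' @param n_subjects cohort size.
#' @param seed master seed; every stage derives sub-seeds from it.
#' @param group_label cohort label carried into outputs (e.g. `"adults"`).
#' @param tr_seconds,n_volumes,grid_shape,voxel_size_mm acquisition settings.
#' @param smoothing_fwhm_mm Gaussian smoothing applied before univariate
#'   analyses (patterns always use unsmoothed fits).
#' @param voxel_p,cluster_alpha,family_alpha inference thresholds.
#' @param cluster_iterations Monte-Carlo iterations for the cluster-extent
#'   threshold.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param smoothness_fwhm_mm assumed smoothness of the group maps for the
#'   cluster simulation; `NULL` estimates it from first-level residuals.
#' @param noise_sd,spatial_fwhm_mm,ar1,pattern_mean,pattern_sd,p_correct
#'   generator settings (see [ground_truth()]).
#' @param sidak_m number of comparisons for the Dunn-Sidak correction of the
#'   Steiger tests; `NULL` uses the number of ROIs actually analyzed.
#' @param crossval_sidak_m comparisons for the cross-validated table;
#'   `NULL` uses the number of (ROI, pair) cells.
#' @param min_cluster_voxels floor on ROI size for pattern analyses.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 12, seed = 1, group_label = "adults",
                            tr_seconds = 1, n_volumes = 244,
                            grid_shape = c(24, 24, 24), voxel_size_mm = 2.5,
                            smoothing_fwhm_mm = 6,
                            voxel_p = 0.001, cluster_alpha = 0.05,
                            family_alpha = 0.05,
                            cluster_iterations = 1000, connectivity = 18,
                            smoothness_fwhm_mm = NULL,
                            noise_sd = 1, spatial_fwhm_mm = 5, ar1 = 0.3,
                            pattern_mean = 1.5, pattern_sd = 0.5,
                            p_correct = 1,
                            sidak_m = NULL, crossval_sidak_m = NULL,
                            min_cluster_voxels = 10) {
  cfg <- as.list(environment())
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_alpha > 0, cluster_alpha < 1,
            family_alpha > 0, family_alpha < 1, n_subjects >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

config_json <- function(config)
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                   null = "null")

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  writeLines(config_json(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$grid_shape <- as.integer(cfg$grid_shape)
  do.call(pipeline_config, cfg)
}

config_spec <- function(config)
  acquisition_spec(config$tr_seconds, config$n_volumes, config$grid_shape,
                   config$voxel_size_mm)

config_truth <- function(config, spec)
  default_ground_truth(spec, seed = config$seed,
                       noise_sd = config$noise_sd,
                       spatial_fwhm_mm = config$spatial_fwhm_mm,
                       ar1_coefficient = config$ar1,
                       pattern_mean = config$pattern_mean,
                       pattern_sd = config$pattern_sd,
                       p_correct = config$p_correct)

# Smooth every volume of a run; returns a bold_run with smoothed data.
smooth_run <- function(run, fwhm_mm) {
  if (fwhm_mm == 0) return(run)
  run$data <- smooth_timeseries(run$data, run$spec$grid_shape, fwhm_mm,
                                run$spec$voxel_size_mm)
  run
}

# First-level processing for one subject: QC, smoothed fits for the two task
# contrasts, unsmoothed pooled and per-run fits for pattern analyses.
# Returns NULL effect maps for tasks whose runs were all excluded.
subject_first_level <- function(subject, config) {
  spec <- config_spec(config)
  out <- list(id = subject$id, effects = list(), fits = list(),
              run_fits = list(), manifest = list())
  for (task in c("arithmetic", "rhyming")) {
    keys <- grep(paste0("^", task, "_"), names(subject$runs), value = TRUE)
    runs <- subject$runs[keys]
    reports <- lapply(runs, function(r)
      flag_outlier_volumes(r$motion, r$global_signal))
    keep <- !vapply(reports, `[[`, logical(1), "run_excluded")
    for (i in seq_along(keys))
      out$manifest[[keys[i]]] <- list(task = task, run = keys[i],
                                      excluded = !keep[i],
                                      fraction_flagged = reports[[i]]$fraction_flagged)
    runs <- runs[keep]; reports <- reports[keep]
    if (!length(runs)) next
    dms <- mapply(function(r, rep) build_design_matrix(r$design, spec,
                                                       motion = r$motion,
                                                       outliers = rep),
                  runs, reports, SIMPLIFY = FALSE)
    smoothed <- lapply(runs, smooth_run, fwhm_mm = config$smoothing_fwhm_mm)
    fit_sm <- fit_glm(smoothed, dms)
    out$effects[[task]] <- contrast_task_vs_control(fit_sm, task)
    fit_raw <- fit_glm(runs, dms)
    out$fits[[task]] <- fit_raw
    out$run_fits[[task]] <- mapply(fit_glm, runs, dms, SIMPLIFY = FALSE)
    out$resid_smoothness <- estimate_smoothness_fwhm(fit_sm$residuals, spec)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort under the config's ground truth, runs QC and
#' first-level GLMs per subject, performs the group conjunction with
#' Monte-Carlo cluster-extent correction, then the naive similarity analysis
#' (Steiger's Z per ROI) and the cross-validated, noise-normalized
#' similarity analysis on the conjunction clusters. All outputs are written
#' as CSV/JSON under `out_dir` and also returned.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return list with `cluster_table`, `steiger_table`, `crossval_table`,
#'   `group_maps`, `conjunction`, `cluster_sim`, `manifest`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  spec <- config_spec(config)
  truth <- config_truth(config, spec)
  cfg_hash <- hash_string(as.character(config_json(config)))
  msg <- function(...) message(sprintf("[neuroverlap %s] ", cfg_hash), ...)

  msg("simulating and fitting ", config$n_subjects, " subjects (seed ",
      config$seed, ")")
  firsts <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    subject <- generate_subject(s, truth, spec, seed = config$seed)
    firsts[[s]] <- subject_first_level(subject, config)
  }
  manifest <- lapply(firsts, function(f)
    list(id = f$id, runs = f$manifest))

  complete <- vapply(firsts, function(f)
    all(c("arithmetic", "rhyming") %in% names(f$effects)), logical(1))
  if (sum(complete) < 2)
    stop_input("pipeline: fewer than 2 subjects with both tasks usable")
  firsts_ok <- firsts[complete]

  msg("group conjunction over ", length(firsts_ok), " subjects")
  eff_a <- lapply(firsts_ok, function(f) f$effects$arithmetic$effect)
  eff_r <- lapply(firsts_ok, function(f) f$effects$rhyming$effect)
  map_a <- group_ttest(eff_a, "arithmetic_vs_control")
  map_r <- group_ttest(eff_r, "rhyming_vs_control")
  mask <- conjunction_mask(map_a, map_r, config$voxel_p,
                           grid_shape = spec$grid_shape)

  fwhm <- config$smoothness_fwhm_mm %||%
    mean(vapply(firsts_ok, `[[`, numeric(1), "resid_smoothness"))
  sim <- estimate_cluster_threshold(spec$grid_shape, spec$voxel_size_mm,
                                    smoothness_fwhm_mm = fwhm,
                                    voxel_p = config$voxel_p,
                                    alpha = config$cluster_alpha,
                                    n_iterations = config$cluster_iterations,
                                    seed = derive_seed(config$seed, "clustsim"),
                                    connectivity = config$connectivity)
  tmin <- pmin(map_a$t, map_r$t)
  clusters <- label_clusters(mask, k_min = sim$k_threshold,
                             stat = array(tmin, spec$grid_shape),
                             connectivity = config$connectivity, spec = spec)
  msg(nrow(clusters), " conjunction cluster(s) at k >= ", sim$k_threshold)

  labels <- attr(clusters, "labels")
  rois <- list()
  for (r in seq_len(nrow(clusters)))
    if (clusters$size_voxels[r] >= config$min_cluster_voxels)
      rois[[paste0("cluster_", r)]] <- which(labels == r)

  steiger_table <- NULL
  crossval_table <- NULL
  if (length(rois)) {
    m1 <- config$sidak_m %||% length(rois)
    alpha1 <- dunn_sidak(config$family_alpha, m1)
    recs <- list(); cv <- list()
    for (roi in names(rois)) {
      vox <- rois[[roi]]
      for (f in firsts_ok) {
        pats <- extract_roi_patterns(f$fits, vox, roi_id = roi)
        recs[[length(recs) + 1]] <- cbind(participant_id = f$id,
                                          similarity_record(pats))
        # per-run patterns for the cross-validated estimate (runs pooled
        # across tasks: run 1 = first retained run of each task, etc.)
        pr <- lapply(1:2, function(k) {
          fits_k <- lapply(f$run_fits, function(rf)
            rf[[min(k, length(rf))]])
          extract_roi_patterns(fits_k, vox, roi_id = roi)$patterns
        })
        resid <- do.call(rbind, lapply(f$fits, function(ft)
          ft$residuals[, vox, drop = FALSE]))
        dof <- sum(sapply(f$fits, `[[`, "dof"))
        cv[[length(cv) + 1]] <-
          crossval_similarity(pr[[1]], pr[[2]], residuals = resid, dof = dof,
                              roi_id = roi, participant_id = f$id)
      }
    }
    recs <- do.call(rbind, recs)
    steiger_table <- do.call(rbind, lapply(names(rois), function(roi)
      group_steiger_test(recs$steiger_z[recs$roi_id == roi],
                         alpha_corrected = alpha1, roi_id = roi)))
    cv <- do.call(rbind, cv)
    m2 <- config$crossval_sidak_m %||% (length(rois) * 2)
    crossval_table <- group_crossval_test(cv,
                                          alpha_corrected = dunn_sidak(config$family_alpha, m2))
    attr(steiger_table, "records") <- recs
    attr(crossval_table, "records") <- cv
  } else msg("no conjunction clusters survive; similarity stages skipped")

  result <- list(cluster_table = clusters, steiger_table = steiger_table,
                 crossval_table = crossval_table,
                 group_maps = list(arithmetic = map_a, rhyming = map_r),
                 conjunction = mask, cluster_sim = sim,
                 manifest = manifest, config_hash = cfg_hash,
                 config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) { if (nrow(df)) df$config_hash <- cfg_hash; df }
    utils::write.csv(stamp(as.data.frame(clusters)),
                     file.path(out_dir, "conjunction_clusters.csv"),
                     row.names = FALSE)
    if (!is.null(steiger_table))
      utils::write.csv(stamp(steiger_table),
                       file.path(out_dir, "steiger_rsa.csv"), row.names = FALSE)
    if (!is.null(crossval_table))
      utils::write.csv(stamp(crossval_table),
                       file.path(out_dir, "crossval_rsa.csv"), row.names = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
    jsonlite::write_json(
      list(package = "neuroverlap",
           version = as.character(utils::packageVersion("neuroverlap")),
           config_hash = cfg_hash, seed = config$seed,
           k_threshold = sim$k_threshold,
           smoothness_fwhm_mm = fwhm,
           decisions = c("FD: sum of absolute parameter differentials, rotations on a 50 mm sphere",
                         "cluster forming threshold: voxelwise one-sided p < voxel_p; cluster-level alpha applied to extent",
                         "patterns: unsmoothed beta estimates; fixation = implicit baseline"),
           manifest = manifest),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  result
}
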