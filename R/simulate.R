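# Synthetic BOLD runs: forward model, noise, motion, cohorts.

#' Construct a BOLD run container
#'
#' @param data T x V numeric matrix (V = prod(grid), column-major voxel
#'   order) or a 4D array (x, y, z, t).
#' @param spec an [acquisition_spec()].
#' @param design a [block_design()].
#' @param motion T x 6 matrix (3 translations mm, 3 rotations rad).
#' @param global_signal length-T numeric series (defaults to the spatial
#'   mean of `data`).
#' @return object of class `bold_run`; `data` is stored as T x V.
#' @export
bold_run <- function(data, spec, design, motion = NULL, global_signal = NULL) {
  if (length(dim(data)) == 4) {
    stopifnot(all(dim(data)[1:3] == spec$grid_shape),
              dim(data)[4] == spec$n_volumes)
    data <- t(matrix(data, prod(spec$grid_shape), spec$n_volumes))
  }
  stopifnot(is.matrix(data), nrow(data) == spec$n_volumes,
            ncol(data) == prod(spec$grid_shape))
  if (!all(is.finite(data))) stop_input("BOLD data contains non-finite values")
  if (is.null(motion)) motion <- matrix(0, nrow(data), 6)
  motion <- as.matrix(motion)
  if (nrow(motion) != nrow(data) || ncol(motion) != 6)
    stop_input("motion must be T x 6")
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  if (is.null(global_signal)) global_signal <- rowMeans(data)
  stopifnot(length(global_signal) == nrow(data))
  structure(list(data = data, spec = spec, design = design,
                 motion = motion, global_signal = global_signal),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %s/%s: %d volumes x %d voxels\n",
              x$design$task, x$design$run_label, nrow(x$data), ncol(x$data)))
  invisible(x)
}

# Deterministic per-(truth, roi) unit pattern fields: shared across the runs
# of one subject because they derive from truth$seed, not the run seed.
truth_patterns <- function(truth, roi) {
  simulate_pattern_set(truth, roi, seed = derive_seed(truth$seed, "patterns", roi))
}

# AR(1)-in-time, spatially smoothed Gaussian noise, re-standardized to
# marginal SD `noise_sd`. Returns T x V.
simulate_noise <- function(spec, noise_sd, ar1, spatial_fwhm_mm) {
  Tn <- spec$n_volumes
  V <- prod(spec$grid_shape)
  if (noise_sd == 0) return(matrix(0, Tn, V))
  eps <- matrix(stats::rnorm(Tn * V), Tn, V)
  if (ar1 > 0) {
    eps <- apply_ar1(eps, ar1)
  }
  if (spatial_fwhm_mm > 0) {
    eps <- smooth_timeseries(eps, spec$grid_shape, spatial_fwhm_mm,
                             spec$voxel_size_mm)
    eps <- eps / smoothing_sd_factor(spatial_fwhm_mm, spec$voxel_size_mm)
  }
  noise_sd * eps
}

# Stationary AR(1) filter columnwise; innovations scaled so the marginal SD
# stays 1 for unit-variance input, with a stationary start.
apply_ar1 <- function(eps, phi) {
  out <- eps * sqrt(1 - phi^2)
  out[1, ] <- eps[1, ]
  for (t in 2:nrow(eps)) out[t, ] <- phi * out[t - 1, ] + out[t, ]
  out
}

#' Generate one synthetic BOLD run
#'
#' Forward model: each condition's boxcar is convolved with the canonical
#' double-gamma HRF; within every ROI responsive to that condition the
#' regressor is scaled by `amplitude[c] * (pattern_mean + pattern_sd * u[c, v])`
#' and added to a constant baseline. Additive noise is Gaussian with AR(1)
#' temporal structure and Gaussian spatial correlation. Subject-specific
#' pattern fields `u` derive from `truth$seed`, so the two runs of a task
#' share them; run-level noise and motion derive from `seed`.
#'
#' Motion is a slow random walk (SD `motion_walk_sd` mm per step); optional
#' `motion_spikes` inject step displacements, and `signal_spikes` inject
#' global intensity deviations, both visible to downstream outlier detection.
#'
#' @param design a [block_design()].
#' @param truth a [ground_truth()].
#' @param spec an [acquisition_spec()].
#' @param seed integer seed for the run-level noise streams.
#' @param baseline constant baseline intensity.
#' @param motion_walk_sd per-volume SD of the motion random walk
#'   (translations, mm); rotations use `motion_walk_sd / 50`.
#' @param motion_spikes optional data.frame with columns `volume` (1-based)
#'   and `mm`: step jumps added to the x translation from that volume on.
#' @param signal_spikes optional data.frame with columns `volume` and `sd`:
#'   global-signal deviations in units of the volume-mean SD.
#' @return a [bold_run()].
#' @export
generate_run <- function(design, truth, spec = acquisition_spec(), seed = 1,
                         baseline = 100, motion_walk_sd = 0.02,
                         motion_spikes = NULL, signal_spikes = NULL) {
  Tn <- spec$n_volumes
  V <- prod(spec$grid_shape)
  conds <- intersect(task_conditions(design$task),
                     unique(design$events$condition))

  # condition regressors from correct trials; incorrect trials contribute the
  # same haemodynamic load but are modelled separately downstream
  regs <- sapply(conds, function(cc) {
    ev <- design$events[design$events$condition == cc, , drop = FALSE]
    hrf_regressor(ev$onset_s, ev$duration_s, spec)
  })
  regs <- matrix(regs, nrow = Tn, dimnames = list(NULL, conds))

  signal <- matrix(0, Tn, V)
  for (roi in names(truth$roi_masks)) {
    amp <- truth$amplitudes[[roi]]
    amp <- amp[names(amp) %in% conds]
    if (!length(amp)) next
    vox <- which(as.vector(truth$roi_masks[[roi]]))
    u <- truth_patterns(truth, roi)
    for (cc in names(amp)) {
      pat <- amp[[cc]] * (truth$pattern_mean + truth$pattern_sd * u[cc, ])
      signal[, vox] <- signal[, vox] + regs[, cc] %o% pat
    }
  }

  with_seed(seed, {
    noise <- simulate_noise(spec, truth$noise_sd, truth$ar1_coefficient,
                            truth$spatial_fwhm_mm)
    data <- baseline + signal + noise

    motion <- matrix(stats::rnorm(Tn * 6, sd = motion_walk_sd), Tn, 6)
    motion[, 4:6] <- motion[, 4:6] / 50
    motion <- apply(motion, 2, cumsum)
    if (!is.null(motion_spikes))
      for (i in seq_len(nrow(motion_spikes))) {
        v <- motion_spikes$volume[i]
        motion[v:Tn, 1] <- motion[v:Tn, 1] + motion_spikes$mm[i]
      }

    gs <- rowMeans(data)
    if (!is.null(signal_spikes)) {
      s <- stats::sd(gs)
      if (s == 0) s <- 1
      for (i in seq_len(nrow(signal_spikes))) {
        v <- signal_spikes$volume[i]
        dev <- signal_spikes$sd[i] * s
        data[v, ] <- data[v, ] + dev
        gs[v] <- gs[v] + dev
      }
    }
    bold_run(data, spec, design, motion = motion, global_signal = gs)
  })
}

#' Generate a cohort of synthetic subjects
#'
#' Each subject receives two arithmetic and two rhyming runs. Subjects are
#' independent draws: each gets its own pattern fields (via a subject seed
#' derived from the master seed) while sharing the cohort's ground-truth
#' parameters. Schedules are randomized per subject and run.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param truth a [ground_truth()]; its `seed` is re-derived per subject.
#' @param spec an [acquisition_spec()].
#' @param seed master seed.
#' @param runs_per_task runs per task (default 2).
#' @return list with elements `subjects` (list of `list(id, runs)`, runs
#'   keyed `arithmetic_1`, `arithmetic_2`, `rhyming_1`, `rhyming_2`) and
#'   `truth`.
#' @export
generate_cohort <- function(n_subjects, truth = NULL,
                            spec = acquisition_spec(), seed = 1,
                            runs_per_task = 2) {
  stopifnot(n_subjects >= 1)
  if (is.null(truth)) truth <- default_ground_truth(spec, seed = seed)
  subjects <- lapply(seq_len(n_subjects), generate_subject, truth = truth,
                     spec = spec, seed = seed, runs_per_task = runs_per_task)
  list(subjects = subjects, truth = truth, spec = spec, seed = seed)
}

#' @rdname generate_cohort
#' @param s subject index (1-based); subject-level seeds derive from the
#'   master `seed` and `s`, so single subjects can be regenerated without
#'   materializing the cohort.
#' @export
generate_subject <- function(s, truth, spec = acquisition_spec(), seed = 1,
                             runs_per_task = 2) {
  sub_id <- sprintf("sub-%02d", s)
  truth_s <- truth
  truth_s$seed <- derive_seed(seed, "subject", s)
  runs <- list()
  for (task in c("arithmetic", "rhyming")) {
    for (r in seq_len(runs_per_task)) {
      d <- make_block_design(task, spec,
                             seed = derive_seed(seed, "design", s, task, r),
                             p_correct = truth$p_correct,
                             run_label = sprintf("%s_run-%02d", sub_id, r))
      runs[[paste0(task, "_", r)]] <-
        generate_run(d, truth_s, spec,
                     seed = derive_seed(seed, "run", s, task, r))
    }
  }
  list(id = sub_id, truth = truth_s, runs = runs)
}
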