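# ART-style volume outlier detection from motion parameters and the global
# BOLD signal.

#' Framewise displacement from realignment parameters
#'
#' Power-style FD: the sum of absolute volume-to-volume differentials of the
#' six realignment parameters, with rotations (radians) converted to arc
#' length on a sphere of `rotation_radius_mm`. The first volume has FD 0.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations (rad).
#' @param rotation_radius_mm sphere radius for the rotation-to-mm
#'   conversion (default 50 mm).
#' @return length-T numeric vector.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) >= 2)
  if (!all(is.finite(motion)))
    stop_input("motion parameters contain non-finite values")
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * rotation_radius_mm
  c(0, rowSums(d))
}

#' Flag outlier volumes (ART rules)
#'
#' A volume is flagged when its framewise displacement exceeds
#' `fd_threshold_mm` (default 1.5 mm) or when its global signal deviates
#' more than `z_threshold` (default 4) SDs from the run mean after
#' z-normalization. A run is marked for exclusion when at least
#' `exclusion_fraction` (default 20%) of its volumes are flagged.
#'
#' When a volume trips both rules, the recorded reason is `"displacement"`.
#'
#' @param motion T x 6 realignment parameters (translations mm, rotations rad).
#' @param global_signal length-T global mean signal.
#' @param fd_threshold_mm,z_threshold,exclusion_fraction rule parameters.
#' @param rotation_radius_mm passed to [framewise_displacement()].
#' @return an `outlier_report`: list with `flagged_volumes` (sorted integer
#'   indices), `reasons` (named character, one entry per flagged volume),
#'   `fraction_flagged`, `run_excluded`, `fd` and the thresholds used.
#' @examples
#' m <- matrix(0, 10, 6); m[5:10, 1] <- 2   # a 2 mm jump at volume 5
#' flag_outlier_volumes(m, rep(100, 10))$flagged_volumes  # 5
#' @export
flag_outlier_volumes <- function(motion, global_signal,
                                 fd_threshold_mm = 1.5, z_threshold = 4,
                                 exclusion_fraction = 0.20,
                                 rotation_radius_mm = 50) {
  fd <- framewise_displacement(motion, rotation_radius_mm)
  Tn <- length(fd)
  if (length(global_signal) != Tn)
    stop_input("global_signal length must match the motion table")
  if (!all(is.finite(global_signal)))
    stop_input("global_signal contains non-finite values")
  gsd <- stats::sd(global_signal)
  z <- if (gsd > 0) (global_signal - mean(global_signal)) / gsd else rep(0, Tn)
  disp <- fd > fd_threshold_mm
  sig <- abs(z) > z_threshold
  flagged <- which(disp | sig)
  reasons <- ifelse(disp[flagged], "displacement", "signal")
  names(reasons) <- as.character(flagged)
  frac <- length(flagged) / Tn
  structure(list(flagged_volumes = flagged,
                 reasons = reasons,
                 fraction_flagged = frac,
                 run_excluded = frac >= exclusion_fraction,
                 fd = fd,
                 thresholds = list(fd_mm = fd_threshold_mm, z = z_threshold,
                                   exclusion_fraction = exclusion_fraction,
                                   rotation_radius_mm = rotation_radius_mm,
                                   fd_convention = "sum-abs-diff, rotations on 50 mm sphere")),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d flagged (%.1f%%); run %s\n",
              length(x$flagged_volumes), 100 * x$fraction_flagged,
              if (x$run_excluded) "EXCLUDED" else "retained"))
  invisible(x)
}
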