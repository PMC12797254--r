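# Tabular and JSON I/O: BIDS-style events and motion TSVs, ground-truth and
# outlier-report JSON.

#' Write / read a BIDS-style events table
#'
#' Events are stored as TSV with columns `onset`, `duration`, `trial_type`,
#' `correct` (onsets in seconds from run start). Reading validates the
#' condition vocabulary for the given task and sorts out-of-order onsets with
#' a warning.
#'
#' @param design a [block_design()].
#' @param path TSV path.
#' @return `write_events`: `path`, invisibly. `read_events`: a
#'   [block_design()].
#' @export
write_events <- function(design, path) {
  ev <- design$events
  utils::write.table(
    data.frame(onset = ev$onset_s, duration = ev$duration_s,
               trial_type = ev$condition, correct = tolower(ev$correct)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param task `"arithmetic"` or `"rhyming"`.
#' @param run_label label for the resulting design.
#' @param run_duration_s optional scheduled duration for validation.
#' @export
read_events <- function(path, task, run_label = basename(path),
                        run_duration_s = NA_real_) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  tab <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE),
                  error = function(e) stop_input("cannot parse events TSV ",
                                                 path, ": ", conditionMessage(e)))
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(tab)))
    stop_input("events TSV must have columns ", paste(need, collapse = ", "))
  if (!nrow(tab)) stop_input("events TSV is empty: ", path)
  correct <- if ("correct" %in% names(tab))
    as.logical(toupper(tab$correct)) else rep(TRUE, nrow(tab))
  block_design(task,
               data.frame(condition = tab$trial_type, onset_s = tab$onset,
                          duration_s = tab$duration, correct = correct),
               run_label = run_label, run_duration_s = run_duration_s)
}

#' Write / read a 6-column motion parameter table
#'
#' @param motion T x 6 matrix (translations mm, rotations rad).
#' @param path TSV path.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(as.matrix(motion), path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("trans_x", "trans_y", "trans_z",
                                   "rot_x", "rot_y", "rot_z"))
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  if (ncol(m) != 6) stop_input("motion table must have 6 columns")
  m
}

#' Serialize an outlier report or ground truth to JSON
#'
#' ROI masks are stored as 1-based linear voxel indices plus the grid shape,
#' keeping the JSON small and exact.
#'
#' @param x an `outlier_report` or `ground_truth`.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, "ground_truth")) {
    out <- unclass(x)
    out$roi_masks <- lapply(x$roi_masks, function(m)
      list(grid_shape = dim(m), voxels = which(m)))
    out$pattern_correlations <-
      list(conditions = rownames(x$pattern_correlations),
           matrix = unname(x$pattern_correlations))
  } else if (inherits(x, "outlier_report")) {
    out <- unclass(x)
    out$reasons <- as.list(x$reasons)
  } else out <- x
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
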