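# First-level design matrices: HRF-convolved condition regressors plus
# nuisance terms (incorrect trials, motion, spike indicators, drift,
# intercept).

#' Build a first-level design matrix for one run
#'
#' Columns, in order: one HRF-convolved regressor per condition present in
#' the run (built from correct trials), an `incorrect` regressor when any
#' trial was answered incorrectly, the six motion parameters (centred), one
#' indicator column per flagged volume, a centred linear drift, and an
#' intercept. Fixation is the implicit baseline: no fixation regressor is
#' included, so a condition beta measures activation versus fixation.
#'
#' Conditions in the task vocabulary but absent from the run are omitted and
#' listed in the result's `omitted_conditions`.
#'
#' @param design a [block_design()].
#' @param spec an [acquisition_spec()].
#' @param motion optional T x 6 motion table.
#' @param outliers optional `outlier_report`; flagged volumes become spike
#'   indicator columns.
#' @return object of class `design_matrix`: list with `matrix` (T x P),
#'   `column_labels`, `condition_columns`, `omitted_conditions`, `hrf_model`.
#' @export
build_design_matrix <- function(design, spec, motion = NULL, outliers = NULL) {
  Tn <- spec$n_volumes
  ev <- design$events
  if (any(ev$onset_s + ev$duration_s > run_duration(spec) + 1e-9))
    stop_input("events extend past the run")
  conds <- task_conditions(design$task)
  present <- conds[conds %in% ev$condition[ev$correct]]
  omitted <- setdiff(conds, present)

  cols <- list()
  for (cc in present) {
    e <- ev[ev$condition == cc & ev$correct, , drop = FALSE]
    cols[[cc]] <- hrf_regressor(e$onset_s, e$duration_s, spec)
  }
  if (any(!ev$correct)) {
    e <- ev[!ev$correct, , drop = FALSE]
    cols[["incorrect"]] <- hrf_regressor(e$onset_s, e$duration_s, spec)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == Tn, ncol(motion) == 6)
    mc <- scale(motion, center = TRUE, scale = FALSE)
    for (j in 1:6) cols[[paste0("motion_", j)]] <- mc[, j]
  }
  if (!is.null(outliers) && length(outliers$flagged_volumes)) {
    for (v in outliers$flagged_volumes) {
      ind <- numeric(Tn); ind[v] <- 1
      cols[[sprintf("spike_%03d", v)]] <- ind
    }
  }
  cols[["drift"]] <- seq_len(Tn) - (Tn + 1) / 2
  cols[["intercept"]] <- rep(1, Tn)

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(matrix = X, column_labels = colnames(X),
                 condition_columns = present,
                 omitted_conditions = omitted,
                 hrf_model = "double-gamma"),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d x %d [%s]\n", nrow(x$matrix),
              ncol(x$matrix), paste(x$column_labels, collapse = ", ")))
  invisible(x)
}

# Stack per-run design matrices for a concatenated multi-run fit: condition
# and incorrect columns are shared across runs (zero outside their run);
# motion, spike, drift and intercept columns become run-specific.
concat_design_matrices <- function(dms) {
  shared_of <- function(dm) intersect(dm$column_labels,
                                      c(ALL_CONDITIONS, "incorrect"))
  shared <- unique(unlist(lapply(dms, shared_of)))
  Ts <- vapply(dms, function(d) nrow(d$matrix), integer(1))
  offs <- c(0, cumsum(Ts))
  total <- sum(Ts)
  Xs <- matrix(0, total, length(shared), dimnames = list(NULL, shared))
  nuis <- list()
  for (r in seq_along(dms)) {
    X <- dms[[r]]$matrix
    rows <- (offs[r] + 1):offs[r + 1]
    for (cc in intersect(colnames(X), shared)) Xs[rows, cc] <- X[, cc]
    for (cc in setdiff(colnames(X), shared)) {
      col <- numeric(total); col[rows] <- X[, cc]
      nuis[[sprintf("run%d_%s", r, cc)]] <- col
    }
  }
  X <- cbind(Xs, do.call(cbind, nuis))
  structure(list(matrix = X, column_labels = colnames(X),
                 condition_columns = intersect(shared, ALL_CONDITIONS),
                 omitted_conditions = character(0),
                 hrf_model = dms[[1]]$hrf_model),
            class = "design_matrix")
}
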