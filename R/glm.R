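# Voxelwise ordinary least squares and contrast t-maps.

#' Fit the first-level GLM
#'
#' Ordinary least squares per voxel. `runs`/`dms` may be single objects (one
#' run) or lists; multiple runs are concatenated in time with shared
#' condition regressors and run-specific nuisance columns (intercept, drift,
#' motion, spikes), mirroring a several-runs-in-one-model subject-level fit.
#'
#' @param runs a [bold_run()] or list of them (same grid).
#' @param dms the matching `design_matrix` or list from
#'   [build_design_matrix()].
#' @return object of class `glm_fit`: `betas` (P x V), `residuals` (T x V),
#'   `sigma2` (length V), `dof`, `design`, `spec`.
#' @export
fit_glm <- function(runs, dms) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  if (inherits(dms, "design_matrix")) dms <- list(dms)
  stopifnot(length(runs) == length(dms), length(runs) >= 1)
  for (i in seq_along(runs))
    if (nrow(runs[[i]]$data) != nrow(dms[[i]]$matrix))
      stop_input("run ", i, ": design matrix rows != run volumes")
  dm <- if (length(dms) == 1) dms[[1]] else concat_design_matrices(dms)
  Y <- do.call(rbind, lapply(runs, function(r) r$data))
  fit_glm_matrix(Y, dm, spec = runs[[1]]$spec)
}

# Core OLS on a T x V response matrix.
fit_glm_matrix <- function(Y, dm, spec = NULL) {
  X <- dm$matrix
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- dm$column_labels[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_input("design matrix is rank deficient; collinear column(s): ",
               paste(dropped, collapse = ", "))
  }
  betas <- qr.coef(qrX, Y)
  resid <- Y - X %*% betas
  dof <- nrow(X) - qrX$rank
  sigma2 <- colSums(resid^2) / dof
  rownames(betas) <- dm$column_labels
  xtx_inv <- solve(crossprod(X))
  structure(list(betas = betas, residuals = resid, sigma2 = sigma2,
                 dof = dof, design = dm, xtx_inv = xtx_inv,
                 spec = spec),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> P = %d, V = %d, dof = %d\n",
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

#' Contrast effect and t-map
#'
#' `effect = c' beta`, `t = effect / sqrt(sigma2 * c' (X'X)^-1 c)`. Weights
#' may be a full numeric vector (length P) or a named vector over a subset
#' of columns; all other weights are 0. Naming a column absent from the fit
#' (e.g. a condition omitted from a run) is an error.
#'
#' @param fit a `glm_fit`.
#' @param weights numeric contrast weights (full or named subset).
#' @return object of class `contrast_map`: `effect`, `t` (length V),
#'   `weights`, `dof`, `se`.
#' @export
compute_contrast <- function(fit, weights) {
  labels <- fit$design$column_labels
  if (!is.null(names(weights))) {
    missing <- setdiff(names(weights), labels)
    if (length(missing))
      stop_input("contrast names absent from the design: ",
                 paste(missing, collapse = ", "))
    w <- stats::setNames(numeric(length(labels)), labels)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != length(labels))
      stop_input("unnamed weights must have length P = ", length(labels))
    w <- stats::setNames(as.numeric(weights), labels)
  }
  if (all(w == 0)) stop_input("contrast must have at least one nonzero weight")
  effect <- drop(crossprod(w, fit$betas))
  cvar <- drop(t(w) %*% fit$xtx_inv %*% w)
  se <- sqrt(fit$sigma2 * cvar)
  tval <- ifelse(se > 0, effect / se, NA_real_)
  structure(list(effect = effect, t = tval, se = se, weights = w,
                 dof = fit$dof, spec = fit$spec),
            class = "contrast_map")
}

#' Standard contrasts of the two-task protocol
#'
#' `contrast_task_vs_control(fit, "arithmetic")` is the mean of the two
#' experimental arithmetic conditions against the PlusOne control
#' (`(Small + Large)/2 - PlusOne`); `"rhyming"` is `Rhyme - LetterMatch`.
#' `contrast_vs_fixation(fit, condition)` is a single condition's beta
#' against the implicit fixation baseline.
#'
#' @param fit a `glm_fit`.
#' @param task `"arithmetic"` or `"rhyming"`.
#' @return a `contrast_map`.
#' @export
contrast_task_vs_control <- function(fit, task) {
  task <- match.arg(task, c("arithmetic", "rhyming"))
  w <- if (task == "arithmetic")
    c(Small = 0.5, Large = 0.5, PlusOne = -1)
  else
    c(Rhyme = 1, LetterMatch = -1)
  compute_contrast(fit, w)
}

#' @rdname contrast_task_vs_control
#' @param condition one of Small, Large, PlusOne, Rhyme, LetterMatch.
#' @export
contrast_vs_fixation <- function(fit, condition) {
  condition <- match.arg(condition, ALL_CONDITIONS)
  compute_contrast(fit, stats::setNames(1, condition))
}
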