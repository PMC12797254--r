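# Cross-validated similarity with multivariate noise normalization:
# shrinkage covariance of GLM residuals, pattern whitening, split-half
# correlation with a zero null baseline, and the group tests.

#' Shrinkage estimate of the voxel noise covariance
#'
#' Sample covariance of first-level GLM residuals over time, shrunk toward
#' its diagonal with an analytically chosen intensity (Ledoit-Wolf /
#' Schafer-Strimmer style): the off-diagonal entries are scaled by
#' `1 - lambda` where `lambda` balances the sampling variance of the
#' covariance entries against their squared magnitude. The whitener is the
#' inverse principal square root of the regularized covariance, computed by
#' eigendecomposition with eigenvalues floored at `eig_floor` times the
#' largest.
#'
#' With very few time points a stable estimate is impossible: the function
#' warns and applies maximal shrinkage (diagonal covariance).
#'
#' @param residuals T x V residual matrix.
#' @param dof residual degrees of freedom of the originating fit.
#' @param shrinkage_lambda optional fixed shrinkage in `[0, 1]`; `NULL`
#'   (default) selects it analytically.
#' @param eig_floor relative eigenvalue floor for the whitener.
#' @return object of class `noise_covariance`: `sigma`, `whitener`,
#'   `shrinkage_lambda`, `dof`.
#' @export
estimate_noise_covariance <- function(residuals, dof,
                                      shrinkage_lambda = NULL,
                                      eig_floor = 1e-6) {
  X <- as.matrix(residuals)
  Tn <- nrow(X); V <- ncol(X)
  if (Tn < 2 || V < 2) stop_input("need T > 1 and at least 2 voxels")
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (Tn - 1)
  if (is.null(shrinkage_lambda)) {
    if (dof < 2 || Tn < 4) {
      warning("too few time points for a stable covariance estimate; ",
              "applying maximal shrinkage", call. = FALSE)
      lambda <- 1
    } else {
      # var of each covariance entry from the T cross-products:
      # sum_t (x_ti x_tj - mean_ij)^2 = sum_t (x_ti x_tj)^2 - T mean_ij^2
      mean_cp <- S * (Tn - 1) / Tn
      W <- crossprod(Xc^2) - Tn * mean_cp^2
      var_s <- W * Tn / ((Tn - 1)^3)
      off <- upper.tri(S)
      num <- sum(var_s[off])
      den <- sum(S[off]^2)
      lambda <- if (den > 0) min(1, max(0, num / den)) else 1
    }
  } else {
    stopifnot(shrinkage_lambda >= 0, shrinkage_lambda <= 1)
    lambda <- shrinkage_lambda
  }
  sigma <- (1 - lambda) * S
  diag(sigma) <- diag(S)
  e <- eigen(sigma, symmetric = TRUE)
  floor_val <- eig_floor * max(e$values)
  vals <- pmax(e$values, floor_val)
  whitener <- e$vectors %*% diag(1 / sqrt(vals), V) %*% t(e$vectors)
  structure(list(sigma = sigma, whitener = whitener,
                 shrinkage_lambda = lambda, dof = dof),
            class = "noise_covariance")
}

#' @export
print.noise_covariance <- function(x, ...) {
  cat(sprintf("<noise_covariance> %d voxels, shrinkage lambda = %.3f\n",
              nrow(x$sigma), x$shrinkage_lambda))
  invisible(x)
}

#' Whiten condition patterns by the noise covariance
#'
#' Right-multiplies each pattern by the whitener `Sigma^{-1/2}`, equalizing
#' and decorrelating voxel noise before similarity estimation.
#'
#' @param patterns condition x voxel matrix.
#' @param cov a `noise_covariance` estimated on the same voxels.
#' @return whitened condition x voxel matrix.
#' @export
whiten_patterns <- function(patterns, cov) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) != nrow(cov$whitener))
    stop_input("pattern voxel count (", ncol(patterns),
               ") does not match covariance dimension (",
               nrow(cov$whitener), ")")
  out <- patterns %*% cov$whitener
  dimnames(out) <- dimnames(patterns)
  out
}

#' Split-half cross-validated pattern similarity
#'
#' Correlates condition `a` estimated from one run with condition `b`
#' estimated from the other, averaged over the two crossings:
#' `r_cv = (cor(a1, b2) + cor(a2, b1)) / 2`. Because the two factors come
#' from independent data halves, noise shared within a run cannot inflate
#' the estimate: the expectation is 0 when the condition patterns are
#' unrelated.
#'
#' @param patterns_run1,patterns_run2 condition x voxel matrices (same
#'   voxels) holding per-run pattern estimates.
#' @param pair character vector of two condition names.
#' @return scalar cross-validated correlation.
#' @export
split_half_similarity <- function(patterns_run1, patterns_run2, pair) {
  stopifnot(length(pair) == 2)
  for (p in list(patterns_run1, patterns_run2))
    if (!all(pair %in% rownames(p)))
      stop_input("both runs must contain conditions ",
                 paste(pair, collapse = " and "))
  a <- pair[1]; b <- pair[2]
  (stats::cor(patterns_run1[a, ], patterns_run2[b, ]) +
      stats::cor(patterns_run2[a, ], patterns_run1[b, ])) / 2
}

#' Naive within-run pattern similarity
#'
#' The non-cross-validated estimate: the mean over runs of the within-run
#' correlation of the two condition patterns. Susceptible to inflation by
#' run-specific shared noise; provided for comparison against
#' [split_half_similarity()].
#'
#' @inheritParams split_half_similarity
#' @return scalar correlation.
#' @export
within_run_similarity <- function(patterns_run1, patterns_run2, pair) {
  stopifnot(length(pair) == 2)
  (stats::cor(patterns_run1[pair[1], ], patterns_run1[pair[2], ]) +
      stats::cor(patterns_run2[pair[1], ], patterns_run2[pair[2], ])) / 2
}

#' Cross-validated similarity for one participant and ROI
#'
#' Convenience wrapper: estimates per-run patterns' noise covariance from the
#' supplied residuals, whitens both runs' patterns, and returns the
#' split-half similarity for each requested pair.
#'
#' @param patterns_run1,patterns_run2 condition x voxel per-run pattern
#'   estimates (unsmoothed effect values).
#' @param residuals optional T x V residual matrix for noise normalization;
#'   `NULL` skips whitening.
#' @param dof residual degrees of freedom (required with `residuals`).
#' @param pairs list of condition pairs (default Small-Rhyme, Large-Rhyme).
#' @param roi_id,participant_id identifiers carried through.
#' @return data.frame with one row per pair: `participant_id`, `roi_id`,
#'   `pair`, `r_cv`, `r_within` (the naive within-run estimate).
#' @export
crossval_similarity <- function(patterns_run1, patterns_run2,
                                residuals = NULL, dof = NULL,
                                pairs = list(c("Small", "Rhyme"),
                                             c("Large", "Rhyme")),
                                roi_id = "roi", participant_id = "sub") {
  if (!is.null(residuals)) {
    stopifnot(!is.null(dof))
    ncov <- estimate_noise_covariance(residuals, dof)
    patterns_run1 <- whiten_patterns(patterns_run1, ncov)
    patterns_run2 <- whiten_patterns(patterns_run2, ncov)
  }
  do.call(rbind, lapply(pairs, function(p)
    data.frame(participant_id = participant_id, roi_id = roi_id,
               pair = paste(p, collapse = "-"),
               r_cv = split_half_similarity(patterns_run1, patterns_run2, p),
               r_within = within_run_similarity(patterns_run1, patterns_run2, p))))
}

#' Group test of cross-validated similarities
#'
#' For every (ROI, pair) cell, Fisher-transforms the per-participant
#' cross-validated correlations and tests them against 0 with a two-sided
#' one-sample t-test. Summary columns (mean, SD, 95% CI) are reported on the
#' correlation scale; t, p and Cohen's d come from the transformed values.
#'
#' @param records data.frame from [crossval_similarity()] rows (columns
#'   `participant_id`, `roi_id`, `pair`, `r_cv`).
#' @param alpha_corrected per-cell significance level, e.g. from
#'   [dunn_sidak()] with m = number of cells.
#' @return data.frame with one row per (roi, pair): `roi_id`, `pair`, `n`,
#'   `mean`, `sd`, `ci_low`, `ci_high`, `t`, `p`, `d`, `alpha_corrected`,
#'   `significant`.
#' @export
group_crossval_test <- function(records, alpha_corrected = 0.05) {
  stopifnot(all(c("participant_id", "roi_id", "pair", "r_cv") %in% names(records)))
  cells <- unique(records[, c("roi_id", "pair")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- records$r_cv[records$roi_id == cells$roi_id[i] &
                        records$pair == cells$pair[i]]
    if (length(r) < 2) stop_input("cell ", cells$roi_id[i], "/",
                                  cells$pair[i], " has < 2 participants")
    if (stats::sd(r) == 0)
      stop_input("cell ", cells$roi_id[i], "/", cells$pair[i],
                 ": zero variance across participants")
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    tt <- stats::t.test(z, mu = 0)
    ci <- stats::t.test(r, mu = 0)$conf.int
    out[[i]] <- data.frame(roi_id = cells$roi_id[i], pair = cells$pair[i],
                           n = length(r), mean = mean(r), sd = stats::sd(r),
                           ci_low = ci[1], ci_high = ci[2],
                           t = unname(tt$statistic), p = tt$p.value,
                           d = mean(z) / stats::sd(z),
                           alpha_corrected = alpha_corrected,
                           significant = tt$p.value < alpha_corrected)
  }
  do.call(rbind, out)
}
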