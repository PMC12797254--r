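# ROI pattern extraction and naive representational similarity: Pearson
# similarities, Fisher transform, Steiger's Z for dependent correlations,
# group t-tests, Dunn-Sidak correction.

#' Extract condition-vs-fixation patterns from an ROI
#'
#' Pulls, for each condition of interest, the vector of condition-vs-fixation
#' effect values over the ROI's voxels from unsmoothed first-level fits.
#' Voxel order is the canonical lexicographic (column-major linear index)
#' order of the mask, identical for every condition. Pass the arithmetic-task
#' fit and the rhyming-task fit (or one combined fit holding all conditions).
#'
#' @param fits a single `glm_fit` containing all requested conditions, or a
#'   list of fits searched in order for each condition.
#' @param mask logical 3D array (or logical/integer vector of voxel indices).
#' @param conditions conditions to extract (default Small, Large, Rhyme).
#' @param roi_id identifier stored in the result.
#' @return object of class `roi_pattern_set`: `patterns` (condition x
#'   voxel), `conditions`, `n_voxels`, `roi_id`, `voxel_index`.
#' @export
extract_roi_patterns <- function(fits, mask,
                                 conditions = c("Small", "Large", "Rhyme"),
                                 roi_id = "roi") {
  if (inherits(fits, "glm_fit")) fits <- list(fits)
  vox <- if (is.logical(mask)) which(mask) else sort(as.integer(mask))
  if (!length(vox)) stop_input("ROI mask is empty")
  P <- matrix(NA_real_, length(conditions), length(vox),
              dimnames = list(conditions, NULL))
  for (cc in conditions) {
    found <- FALSE
    for (f in fits) {
      if (cc %in% rownames(f$betas)) {
        if (max(vox) > ncol(f$betas))
          stop_input("mask indices outside the fitted grid")
        P[cc, ] <- f$betas[cc, vox]
        found <- TRUE
        break
      }
    }
    if (!found) stop_input("condition '", cc, "' not present in any fit")
  }
  if (!all(is.finite(P))) {
    bad <- vox[colSums(!is.finite(P)) > 0]
    stop_input("non-finite effects at voxel(s) ",
               paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(roi_id = roi_id, conditions = conditions, patterns = P,
                 n_voxels = length(vox), voxel_index = vox),
            class = "roi_pattern_set")
}

#' Fisher's r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`. Transformed similarities
#' may extend beyond +/-1 even though correlations cannot.
#'
#' @param r correlation(s), each strictly inside (-1, 1).
#' @return numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop_input("fisher_z requires |r| < 1")
  atanh(r)
}

#' Steiger's Z for two dependent correlations sharing a variable
#'
#' Compares `r12` and `r13` (both involving variable 1) estimated on the
#' same n sampling units, using the pooled-estimate form: with Fisher
#' transforms `z12`, `z13`, pooled `rbar = (r12 + r13) / 2`,
#' `psi = r23 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r23^2) / 2` and
#' `s = psi / (1 - rbar^2)^2`,
#' `Z = (z12 - z13) * sqrt((n - 3) / (2 - 2 s))`.
#'
#' In the two-task similarity analysis, variable 1 is the Rhyme pattern, 2
#' Small and 3 Large, and n is the ROI voxel count; positive Z means the
#' rhyming pattern is more similar to Small than to Large.
#'
#' @param r12,r13 the two dependent correlations being compared.
#' @param r23 the correlation between variables 2 and 3.
#' @param n number of sampling units (>= 4).
#' @return the Z statistic (scalar).
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (n < 4) stop_input("steiger_z needs n >= 4")
  if (any(abs(c(r12, r13, r23)) >= 1))
    stop_input("steiger_z requires all |r| < 1")
  z12 <- atanh(r12); z13 <- atanh(r13)
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - rbar^2 * (1 - 2 * rbar^2 - r23^2) / 2
  s <- psi / (1 - rbar^2)^2
  if (2 - 2 * s <= 0)
    stop_input("degenerate correlation triple: 2 - 2*s <= 0 (s = ",
               signif(s, 4), ")")
  (z12 - z13) * sqrt((n - 3) / (2 - 2 * s))
}

#' Per-participant similarity record for one ROI
#'
#' Computes the three pairwise Pearson similarities between the Small, Large
#' and Rhyme patterns, their Fisher transforms, and Steiger's Z contrasting
#' the Small-Rhyme against the Large-Rhyme similarity (shared variable:
#' Rhyme; n = ROI voxel count).
#'
#' @param pats a `roi_pattern_set` from [extract_roi_patterns()].
#' @return object of class `similarity_record` (a one-row data.frame with
#'   columns `roi_id`, `n_voxels`, `r_small_rhyme`, `r_large_rhyme`,
#'   `r_small_large`, `z_small_rhyme`, `z_large_rhyme`, `z_small_large`,
#'   `steiger_z`).
#' @export
similarity_record <- function(pats) {
  P <- pats$patterns
  stopifnot(all(c("Small", "Large", "Rhyme") %in% rownames(P)))
  r_sr <- stats::cor(P["Small", ], P["Rhyme", ])
  r_lr <- stats::cor(P["Large", ], P["Rhyme", ])
  r_sl <- stats::cor(P["Small", ], P["Large", ])
  rec <- data.frame(roi_id = pats$roi_id, n_voxels = pats$n_voxels,
                    r_small_rhyme = r_sr, r_large_rhyme = r_lr,
                    r_small_large = r_sl,
                    z_small_rhyme = fisher_z(r_sr),
                    z_large_rhyme = fisher_z(r_lr),
                    z_small_large = fisher_z(r_sl),
                    steiger_z = steiger_z(r_sr, r_lr, r_sl, pats$n_voxels))
  class(rec) <- c("similarity_record", "data.frame")
  rec
}

#' Group test of per-participant Steiger coefficients
#'
#' Two-sided one-sample t-test of the per-participant Z coefficients against
#' 0. A positive mean indicates greater neural similarity between the rhyming
#' pattern and small problems than between rhyming and large problems.
#'
#' @param zs numeric vector of per-participant Steiger Z values.
#' @param alpha_corrected significance level after multiplicity correction
#'   (e.g. from [dunn_sidak()]).
#' @param roi_id identifier carried through.
#' @return a one-row data.frame: `roi_id`, `n_participants`, `mean`, `sd`,
#'   `t`, `p`, `alpha_corrected`, `significant`.
#' @export
group_steiger_test <- function(zs, alpha_corrected = 0.05, roi_id = "roi") {
  n <- length(zs)
  if (n < 2) stop_input("group test needs >= 2 participants")
  if (stats::sd(zs) == 0)
    stop_input("degenerate input: zero variance across participants")
  tt <- stats::t.test(zs, mu = 0)
  data.frame(roi_id = roi_id, n_participants = n,
             mean = mean(zs), sd = stats::sd(zs),
             t = unname(tt$statistic), p = tt$p.value,
             alpha_corrected = alpha_corrected,
             significant = tt$p.value < alpha_corrected)
}

#' Dunn-Sidak corrected per-comparison alpha
#'
#' `1 - (1 - alpha_family)^(1/m)`: the per-comparison level that keeps the
#' family-wise error at `alpha_family` for m independent tests. With a
#' family alpha of 0.05, m = 3 gives 0.017 and m = 4 gives 0.013 (3 and 2
#' significant figures).
#'
#' @param alpha_family family-wise error level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return corrected per-comparison alpha.
#' @export
dunn_sidak <- function(alpha_family, m) {
  stopifnot(alpha_family > 0, alpha_family < 1, m >= 1)
  1 - (1 - alpha_family)^(1 / m)
}
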