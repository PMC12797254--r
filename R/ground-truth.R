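# Ground-truth world for the synthetic generator: activation geometry,
# condition amplitudes, and the cross-condition pattern-correlation structure.

#' Build a condition pattern-correlation matrix
#'
#' Assembles a full correlation matrix over the five task conditions from the
#' three pairs of scientific interest, filling the remaining pairs (those
#' involving the control conditions) with a common background value.
#'
#' @param small_large,small_rhyme,large_rhyme target Pearson correlations in
#'   (-1, 1) between the corresponding condition patterns.
#' @param background correlation assigned to all other condition pairs.
#' @param conditions condition names (default: all five).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pattern_correlation_matrix <- function(small_large = 0.6, small_rhyme = 0.3,
                                       large_rhyme = 0.5, background = 0.2,
                                       conditions = ALL_CONDITIONS) {
  C <- matrix(background, length(conditions), length(conditions),
              dimnames = list(conditions, conditions))
  diag(C) <- 1
  set_pair <- function(a, b, r) {
    if (all(c(a, b) %in% conditions)) C[a, b] <<- C[b, a] <<- r
  }
  set_pair("Small", "Large", small_large)
  set_pair("Small", "Rhyme", small_rhyme)
  set_pair("Large", "Rhyme", large_rhyme)
  validate_correlation_matrix(C)
  C
}

# Validate symmetry, range and positive semi-definiteness; on failure, name
# the offending pair (2x2 check) or triple (principal 3x3 minors) so the user
# sees which request is inconsistent.
validate_correlation_matrix <- function(C, tol = 1e-8) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (is.null(rownames(C))) stop_input("correlation matrix needs condition names")
  if (max(abs(C - t(C))) > tol) stop_input("correlation matrix is not symmetric")
  if (any(abs(diag(C) - 1) > tol)) stop_input("correlation matrix diagonal must be 1")
  nm <- rownames(C)
  for (i in seq_len(nrow(C) - 1)) for (j in (i + 1):nrow(C))
    if (abs(C[i, j]) > 1 + tol)
      stop_input("requested correlation for pair ", nm[i], "-", nm[j],
                 " is outside [-1, 1]")
  if (nrow(C) >= 3) {
    combs <- utils::combn(nrow(C), 3)
    for (k in seq_len(ncol(combs))) {
      idx <- combs[, k]
      if (det(C[idx, idx]) < -tol)
        stop_input("requested correlations are not jointly attainable ",
                   "(non-positive-semi-definite) for the triple ",
                   paste(nm[idx], collapse = ", "))
    }
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stop_input("requested correlation matrix is not positive semi-definite ",
               "(min eigenvalue ", signif(min(ev), 3), ") over conditions ",
               paste(nm, collapse = ", "))
  invisible(TRUE)
}

#' Ground truth for the synthetic cohort
#'
#' The stated world of the generator: where activation lives (`roi_masks`),
#' how strongly each condition drives each region (`amplitudes`), how the
#' multi-voxel patterns of different conditions correlate
#' (`pattern_correlations`), and the noise model (temporal AR(1), spatial
#' smoothness, marginal SD).
#'
#' Within a responsive ROI, the signal carried by voxel v for condition c is
#' `amplitude[c] * (pattern_mean + pattern_sd * u[c, v])`, where the unit
#' fields `u` have the requested cross-condition correlation structure.
#' `pattern_mean` sets the homogeneous (univariate) part of the response;
#' `pattern_sd` the heterogeneous multi-voxel part that similarity analyses
#' read out.
#'
#' @param roi_masks named list of logical 3D arrays (one per ROI).
#' @param amplitudes either a single named numeric vector of condition
#'   amplitudes applied to every ROI, or a named list (per ROI) of such
#'   vectors. Conditions absent from an ROI's vector do not drive it.
#' @param pattern_correlations correlation matrix over conditions, e.g. from
#'   [pattern_correlation_matrix()].
#' @param noise_sd marginal SD of the additive noise (signal units).
#' @param spatial_fwhm_mm FWHM of the Gaussian spatial correlation of the
#'   noise (0 = white).
#' @param ar1_coefficient lag-1 temporal autocorrelation in `[0, 1)`.
#' @param pattern_mean,pattern_sd homogeneous and heterogeneous response
#'   components (see Details).
#' @param p_correct per-trial probability of a correct response.
#' @param seed integer seed from which subject/ROI pattern streams derive.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(roi_masks, amplitudes,
                         pattern_correlations = pattern_correlation_matrix(),
                         noise_sd = 1, spatial_fwhm_mm = 5,
                         ar1_coefficient = 0.3,
                         pattern_mean = 1.5, pattern_sd = 0.5,
                         p_correct = 1, seed = 1) {
  stopifnot(is.list(roi_masks), length(roi_masks) > 0)
  if (is.null(names(roi_masks)) || any(names(roi_masks) == ""))
    stop_input("roi_masks must be a named list")
  for (nm in names(roi_masks))
    if (!is.logical(roi_masks[[nm]]) || length(dim(roi_masks[[nm]])) != 3)
      stop_input("roi_masks[['", nm, "']] must be a logical 3D array")
  if (!is.list(amplitudes))
    amplitudes <- stats::setNames(rep(list(amplitudes), length(roi_masks)),
                                  names(roi_masks))
  if (!setequal(names(amplitudes), names(roi_masks)))
    stop_input("amplitudes (as a list) must be named like roi_masks")
  for (nm in names(amplitudes)) {
    a <- amplitudes[[nm]]
    if (is.null(names(a)) || !all(names(a) %in% ALL_CONDITIONS))
      stop_input("amplitudes for ROI '", nm, "' must be named by condition")
  }
  validate_correlation_matrix(pattern_correlations)
  stopifnot(noise_sd >= 0, spatial_fwhm_mm >= 0,
            ar1_coefficient >= 0, ar1_coefficient < 1,
            pattern_sd >= 0, p_correct >= 0, p_correct <= 1)
  structure(list(roi_masks = roi_masks, amplitudes = amplitudes,
                 pattern_correlations = pattern_correlations,
                 noise_sd = noise_sd, spatial_fwhm_mm = spatial_fwhm_mm,
                 ar1_coefficient = ar1_coefficient,
                 pattern_mean = pattern_mean, pattern_sd = pattern_sd,
                 p_correct = p_correct, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d ROI(s): %s; noise_sd %g, FWHM %g mm, AR1 %g\n",
              length(x$roi_masks), paste(names(x$roi_masks), collapse = ", "),
              x$noise_sd, x$spatial_fwhm_mm, x$ar1_coefficient))
  invisible(x)
}

# Axis-aligned box mask helper (1-based inclusive voxel ranges).
box_mask <- function(grid_shape, x, y, z) {
  m <- array(FALSE, dim = grid_shape)
  m[x[1]:x[2], y[1]:y[2], z[1]:z[2]] <- TRUE
  m
}

#' Default planted activation geometry
#'
#' Builds the default `ground_truth` on a spec's grid: bilateral "arithmetic"
#' regions, one left-lateralized "rhyming" region, and one left-frontal
#' overlap region driven by both tasks. Experimental conditions drive their
#' regions at amplitude 1.5 and control conditions (PlusOne, LetterMatch) at
#' 0.75, so both task contrasts are positive in their regions and the
#' conjunction is positive only in the overlap region.
#'
#' @param spec an [acquisition_spec()]; the default 24^3 grid is assumed
#'   large enough to hold the boxes (>= 20 voxels per axis).
#' @param seed master seed stored in the truth.
#' @param ... further arguments passed to [ground_truth()] (noise model,
#'   pattern components, correlation structure).
#' @return a `ground_truth`.
#' @export
default_ground_truth <- function(spec = acquisition_spec(), seed = 1, ...) {
  g <- spec$grid_shape
  if (any(g < 20)) stop_input("default geometry needs a grid of at least 20^3")
  masks <- list(
    # left-frontal overlap: both tasks (6x6x6 = 216 voxels)
    overlap_left  = box_mask(g, c(4, 9),        c(14, 19), c(12, 17)),
    # bilateral arithmetic-only regions (parietal stand-ins)
    arith_left    = box_mask(g, c(4, 8),        c(5, 9),   c(13, 17)),
    arith_right   = box_mask(g, c(g[1] - 7, g[1] - 3), c(5, 9), c(13, 17)),
    # left rhyming-only region (temporal stand-in)
    rhyme_left    = box_mask(g, c(4, 8),        c(8, 12),  c(5, 9))
  )
  arith_amp <- c(Small = 1.5, Large = 1.5, PlusOne = 0.75)
  rhyme_amp <- c(Rhyme = 1.5, LetterMatch = 0.75)
  amplitudes <- list(overlap_left = c(arith_amp, rhyme_amp),
                     arith_left   = arith_amp,
                     arith_right  = arith_amp,
                     rhyme_left   = rhyme_amp)
  ground_truth(masks, amplitudes, seed = seed, ...)
}

#' Simulate correlation-structured condition patterns for one ROI
#'
#' Draws one multi-voxel pattern per condition over the ROI's voxels such
#' that, across voxels, the expected Pearson correlation of any pair equals
#' the requested entry of `truth$pattern_correlations`. Patterns are built by
#' mixing independent standard-normal voxel fields through the symmetric
#' square root of the target correlation matrix, so the construction is exact
#' in expectation for any positive semi-definite request.
#'
#' The returned patterns are the unit fields `u` (zero mean, unit variance
#' per voxel); [generate_run()] composes them with `pattern_mean`,
#' `pattern_sd` and the condition amplitudes.
#'
#' @param truth a [ground_truth()].
#' @param roi ROI name (must exist in `truth$roi_masks`).
#' @param seed integer seed.
#' @param conditions conditions to simulate (default: rows of the
#'   correlation matrix).
#' @return matrix, conditions x voxels, with condition rownames; voxel
#'   columns follow the lexicographic (column-major linear index) order of
#'   the ROI mask.
#' @export
simulate_pattern_set <- function(truth, roi, seed,
                                 conditions = rownames(truth$pattern_correlations)) {
  if (!roi %in% names(truth$roi_masks))
    stop_input("unknown ROI '", roi, "'")
  C <- truth$pattern_correlations[conditions, conditions, drop = FALSE]
  validate_correlation_matrix(C)
  n_vox <- sum(truth$roi_masks[[roi]])
  e <- eigen(C, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C)) %*% t(e$vectors)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(nrow(C) * n_vox), nrow(C), n_vox)
    U <- A %*% Z
    rownames(U) <- conditions
    U
  })
}
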