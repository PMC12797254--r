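# Group-level inference: one-sample t-maps, minimum-statistic conjunction,
# and Monte-Carlo cluster-extent correction.

#' Voxelwise one-sample group t-test
#'
#' Tests subject effect maps against 0 at every voxel. Voxels with zero
#' between-subject variance get `NA` t and p and are reported in
#' `degenerate_voxels`.
#'
#' @param maps list of subject effect vectors/arrays (one per subject, common
#'   grid) or an n x V matrix.
#' @param contrast_label identifier carried in the result.
#' @return object of class `group_stat_map`: `t`, `p_one_sided` (length V),
#'   `n_subjects`, `dof`, `contrast_label`, `degenerate_voxels`.
#' @export
group_ttest <- function(maps, contrast_label = "contrast") {
  if (is.list(maps)) {
    lens <- vapply(maps, length, integer(1))
    if (length(unique(lens)) != 1)
      stop_input("subject maps differ in size (grid mismatch)")
    maps <- do.call(rbind, lapply(maps, as.vector))
  }
  n <- nrow(maps)
  if (n < 2) stop_input("group t-test needs at least 2 subjects")
  m <- colMeans(maps)
  s <- sqrt(colSums(sweep(maps, 2, m)^2) / (n - 1))
  tval <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  p <- stats::pt(tval, df = n - 1, lower.tail = FALSE)
  structure(list(t = tval, p_one_sided = p, n_subjects = n, dof = n - 1,
                 contrast_label = contrast_label,
                 degenerate_voxels = which(!(s > 0))),
            class = "group_stat_map")
}

#' Minimum-statistic conjunction mask
#'
#' TRUE exactly where both one-sided p-values fall below `voxel_p` — the
#' conservative "both contrasts individually significant" conjunction test.
#'
#' @param mapA,mapB `group_stat_map`s on a common grid.
#' @param voxel_p voxelwise threshold (default 0.001).
#' @param grid_shape optional 3-vector; if given the mask is returned as a
#'   3D logical array.
#' @return logical vector (or array).
#' @export
conjunction_mask <- function(mapA, mapB, voxel_p = 0.001, grid_shape = NULL) {
  if (length(mapA$p_one_sided) != length(mapB$p_one_sided))
    stop_input("maps are on different grids")
  m <- !is.na(mapA$p_one_sided) & !is.na(mapB$p_one_sided) &
    mapA$p_one_sided < voxel_p & mapB$p_one_sided < voxel_p
  if (!is.null(grid_shape)) m <- array(m, dim = grid_shape)
  m
}

# neighbour offsets for 6 (faces), 18 (faces+edges), 26 (full cube)
connectivity_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1,
                 stop_input("connectivity must be 6, 18 or 26"))
  offs[keep, , drop = FALSE]
}

# Connected components of a logical 3D mask; returns integer array of labels
# (0 outside). Components found via igraph on the voxel adjacency edges.
label_components <- function(mask, connectivity = 18) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dim = d)
  if (!length(idx)) return(lab)
  coord <- arrayInd(idx, d)
  offs <- connectivity_offsets(connectivity)
  # keep each undirected edge once: offsets lexicographically positive
  pos <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
              drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(pos))) {
    nb <- sweep(coord, 2, pos[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_idx <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    hit <- match(nb_idx, idx)
    sel <- !is.na(hit)
    from <- c(from, which(ok)[sel])
    to <- c(to, hit[sel])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Label suprathreshold clusters
#'
#' Connected components of a binary mask under the configured connectivity
#' (default 18: faces + edges). Components smaller than `k_min` are
#' discarded. Each cluster's peak is its maximum `|stat|` voxel, ties broken
#' by lexicographic (column-major) voxel index. Clusters are ordered by
#' decreasing size.
#'
#' @param mask logical 3D array.
#' @param k_min minimum cluster extent in voxels.
#' @param stat numeric array of voxel statistics (same grid) used for peaks;
#'   optional — without it peaks are the lexicographically first voxel.
#' @param connectivity 6, 18 or 26.
#' @param spec optional [acquisition_spec()] for mm peak coordinates.
#' @return object of class `cluster_table`: a data.frame with columns
#'   `cluster_id`, `size_voxels`, `peak_i/j/k` (0-based voxel indices),
#'   `peak_x/y/z_mm` (if `spec` given), `peak_stat`; the label array is
#'   attached as attribute `labels`.
#' @export
label_clusters <- function(mask, k_min = 1, stat = NULL, connectivity = 18,
                           spec = NULL) {
  lab <- label_components(mask, connectivity)
  d <- dim(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- list()
  for (id in ids) {
    vox <- which(lab == id)
    if (length(vox) < k_min) {
      lab[vox] <- 0L
      next
    }
    if (!is.null(stat)) {
      s <- abs(as.vector(stat)[vox])
      peak <- vox[which.max(s)]  # which.max takes the first max: lexicographic
      pstat <- as.vector(stat)[peak]
    } else {
      peak <- vox[1]
      pstat <- NA_real_
    }
    ijk <- arrayInd(peak, d) - 1L
    rows[[length(rows) + 1]] <-
      data.frame(old_id = id, size_voxels = length(vox),
                 peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
                 peak_stat = pstat)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(old_id = integer(0), size_voxels = integer(0),
                  peak_i = integer(0), peak_j = integer(0),
                  peak_k = integer(0), peak_stat = numeric(0))
  tab <- tab[order(-tab$size_voxels, tab$old_id), , drop = FALSE]
  rownames(tab) <- NULL
  # relabel the array to match the table ordering
  out_lab <- array(0L, dim = d)
  for (r in seq_len(nrow(tab))) out_lab[lab == tab$old_id[r]] <- r
  tab$cluster_id <- seq_len(nrow(tab))
  tab$old_id <- NULL
  tab <- tab[, c("cluster_id", setdiff(names(tab), "cluster_id")), drop = FALSE]
  if (!is.null(spec) && nrow(tab)) {
    mm <- voxel_to_mm(as.matrix(tab[, c("peak_i", "peak_j", "peak_k")]), spec)
    tab$peak_x_mm <- mm[, 1]; tab$peak_y_mm <- mm[, 2]; tab$peak_z_mm <- mm[, 3]
  }
  structure(tab, class = c("cluster_table", "data.frame"), labels = out_lab)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Emulates a 3dClustSim-style simulation: on each iteration a Gaussian white
#' volume is smoothed to the target FWHM, re-standardized, thresholded at the
#' one-sided `voxel_p` quantile, and the maximum suprathreshold cluster size
#' recorded. The cluster-extent threshold `k` is the ceiling of the
#' `1 - alpha` quantile of the null maximum-size distribution (and at least
#' 1).
#'
#' @param grid_shape 3 integers.
#' @param voxel_size_mm voxel edge, mm.
#' @param smoothness_fwhm_mm assumed smoothness of the statistic image, mm.
#' @param voxel_p cluster-forming (voxelwise) one-sided threshold.
#' @param alpha cluster-level family-wise error target.
#' @param n_iterations Monte-Carlo iterations (>= 1000).
#' @param seed integer seed.
#' @param connectivity cluster connectivity (default 18).
#' @return object of class `cluster_sim_result`: `k_threshold`,
#'   `null_max_sizes`, and the simulation parameters.
#' @export
estimate_cluster_threshold <- function(grid_shape, voxel_size_mm,
                                       smoothness_fwhm_mm,
                                       voxel_p = 0.001, alpha = 0.05,
                                       n_iterations = 2000, seed = 1,
                                       connectivity = 18) {
  if (n_iterations < 1000)
    stop_input("n_iterations must be at least 1000 for a stable tail quantile")
  zthr <- stats::qnorm(1 - voxel_p)
  with_seed(seed, {
    max_sizes <- integer(n_iterations)
    for (it in seq_len(n_iterations)) {
      vol <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
      if (smoothness_fwhm_mm > 0) {
        vol <- smooth_volume(vol, smoothness_fwhm_mm, voxel_size_mm)
        vol <- (vol - mean(vol)) / stats::sd(vol)
      }
      mask <- vol > zthr
      if (!any(mask)) next
      lab <- label_components(mask, connectivity)
      max_sizes[it] <- max(tabulate(lab[lab > 0]))
    }
    k <- max(1, ceiling(stats::quantile(max_sizes, 1 - alpha, names = FALSE,
                                        type = 1)))
    structure(list(k_threshold = as.integer(k), null_max_sizes = max_sizes,
                   alpha = alpha, voxel_p = voxel_p,
                   smoothness_fwhm_mm = smoothness_fwhm_mm,
                   grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                   n_iterations = n_iterations, connectivity = connectivity,
                   seed = seed),
              class = "cluster_sim_result")
  })
}

#' @export
print.cluster_sim_result <- function(x, ...) {
  cat(sprintf("<cluster_sim_result> k = %d (alpha %g, voxel p %g, FWHM %g mm, %d iter)\n",
              x$k_threshold, x$alpha, x$voxel_p, x$smoothness_fwhm_mm,
              x$n_iterations))
  invisible(x)
}

#' Estimate image smoothness from residual spatial autocorrelation
#'
#' Fits a Gaussian autocorrelation model to the lag-1 spatial correlation of
#' residual volumes. A field produced by Gaussian smoothing with kernel SD
#' `sigma` has autocorrelation `exp(-d^2 / (4 sigma^2))` (the kernel's
#' self-convolution), i.e. `corr(lag d) = exp(-2 log(2) d^2 / f^2)` at FWHM
#' f. The estimate is averaged over axes and volumes.
#'
#' @param resid T x V residual matrix.
#' @param spec an [acquisition_spec()].
#' @param n_sample number of volumes to sample for the estimate.
#' @return estimated FWHM in mm (0 when residuals are spatially white or
#'   negatively correlated).
#' @export
estimate_smoothness_fwhm <- function(resid, spec, n_sample = 20) {
  d <- spec$grid_shape
  take <- unique(round(seq(1, nrow(resid), length.out = min(n_sample, nrow(resid)))))
  rho <- numeric(0)
  for (t in take) {
    vol <- array(resid[t, ], dim = d)
    for (ax in 1:3) {
      v <- aperm(vol, c(ax, setdiff(1:3, ax)))
      a <- as.vector(v[-dim(v)[1], , ]); b <- as.vector(v[-1, , ])
      rho <- c(rho, stats::cor(a, b))
    }
  }
  r <- mean(rho)
  if (!is.finite(r) || r <= 0) return(0)
  sqrt(2 * log(2) * spec$voxel_size_mm^2 / (-log(r)))
}
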