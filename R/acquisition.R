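#' Acquisition specification
#'
#' Describes one run's sampling: repetition time, number of volumes, the
#' voxel grid, and isotropic voxel size. Defaults mirror a 3 T multiband
#' block-design protocol (TR = 1 s, 244 volumes, 2.5 mm voxels) with a
#' desk-scale 24^3 grid standing in for the full acquisition matrix.
#'
#' @param tr_seconds repetition time in seconds (> 0).
#' @param n_volumes number of volumes per run (>= 1).
#' @param grid_shape integer vector of length 3, each >= 4.
#' @param voxel_size_mm isotropic voxel edge in mm (> 0).
#' @return an object of class `acquisition_spec`.
#' @examples
#' spec <- acquisition_spec()
#' run_duration(spec)  # 244 s
#' @export
acquisition_spec <- function(tr_seconds = 1, n_volumes = 244,
                             grid_shape = c(24L, 24L, 24L),
                             voxel_size_mm = 2.5) {
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop_input("tr_seconds must be a positive scalar")
  if (!is.numeric(n_volumes) || length(n_volumes) != 1 || n_volumes < 1 ||
      n_volumes != round(n_volumes))
    stop_input("n_volumes must be a positive integer")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stop_input("grid_shape must be 3 integers, each >= 4")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop_input("voxel_size_mm must be positive")
  structure(list(tr_seconds = tr_seconds,
                 n_volumes = as.integer(n_volumes),
                 grid_shape = grid_shape,
                 voxel_size_mm = voxel_size_mm),
            class = "acquisition_spec")
}

#' @rdname acquisition_spec
#' @param spec an `acquisition_spec`.
#' @export
run_duration <- function(spec) spec$n_volumes * spec$tr_seconds

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> TR = %g s, %d volumes, grid %s, voxel %g mm\n",
              x$tr_seconds, x$n_volumes,
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm))
  invisible(x)
}

# RAS+ affine for an isotropic grid centred on the origin (4x4).
grid_affine <- function(spec) {
  v <- spec$voxel_size_mm
  origin <- -(spec$grid_shape - 1) / 2 * v
  rbind(c(v, 0, 0, origin[1]),
        c(0, v, 0, origin[2]),
        c(0, 0, v, origin[3]),
        c(0, 0, 0, 1))
}

# voxel (0-based ijk, rows) -> mm using the spec's affine
voxel_to_mm <- function(ijk, spec) {
  ijk <- matrix(ijk, ncol = 3)
  aff <- grid_affine(spec)
  t(aff[1:3, 1:3] %*% t(ijk) + aff[1:3, 4])
}
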