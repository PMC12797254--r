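# Minimal NIfTI-1 single-file (.nii) reader/writer. Only the subset the
# pipeline needs: 3D/4D float32/float64/int16 data, sform affine, no
# compression. No R NIfTI package is assumed available at run time.

NIFTI_HDR_SIZE <- 348L

#' Write a volume or BOLD run as NIfTI-1
#'
#' Writes an uncompressed `.nii` with an RAS+ sform affine derived from the
#' acquisition spec (isotropic voxels, grid centred on the origin) and
#' float32 data. 4D data is stored (x, y, z, t).
#'
#' @param x a [bold_run()], a 3D/4D array, or a T x V matrix (needs `spec`).
#' @param path output file path.
#' @param spec an [acquisition_spec()]; taken from `x` when it is a
#'   `bold_run`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spec = NULL) {
  if (inherits(x, "bold_run")) {
    spec <- x$spec
    data <- array(t(x$data), dim = c(spec$grid_shape, spec$n_volumes))
  } else if (is.matrix(x) && !is.null(spec)) {
    data <- array(t(x), dim = c(spec$grid_shape, nrow(x)))
  } else if (is.array(x)) {
    data <- x
    if (is.null(spec))
      spec <- acquisition_spec(n_volumes = if (length(dim(x)) == 4) dim(x)[4] else 1,
                               grid_shape = dim(x)[1:3])
  } else stop_input("cannot interpret input for write_nifti")
  nd <- length(dim(data))
  stopifnot(nd %in% c(3, 4))
  dims <- c(nd, dim(data), rep(1L, 7 - nd))
  aff <- grid_affine(spec)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(NIFTI_HDR_SIZE, con, size = 4)              # sizeof_hdr
  writeBin(raw(36), con)                               # unused legacy fields
  writeBin(as.integer(dims), con, size = 2)            # dim[8]
  writeBin(numeric(3), con, size = 4)                  # intent_p1..p3
  writeBin(integer(1), con, size = 2)                  # intent_code
  writeBin(16L, con, size = 2)                         # datatype = float32
  writeBin(32L, con, size = 2)                         # bitpix
  writeBin(integer(1), con, size = 2)                  # slice_start
  pixdim <- c(1, rep(spec$voxel_size_mm, 3), spec$tr_seconds, 1, 1, 1)
  writeBin(pixdim, con, size = 4)                      # pixdim[8]
  writeBin(352, con, size = 4)                         # vox_offset
  writeBin(c(1, 0), con, size = 4)                     # scl_slope, scl_inter
  writeBin(integer(1), con, size = 2)                  # slice_end
  writeBin(as.raw(c(0L, 10L)), con)                    # slice_code = 0, units mm|s
  writeBin(numeric(3), con, size = 4)                  # cal_max/min, slice_duration
  writeBin(numeric(1), con, size = 4)                  # toffset
  writeBin(integer(2), con, size = 4)                  # glmax, glmin
  writeBin(charToRaw(sprintf("%-80s", "neuroverlap synthetic volume")), con)
  writeBin(raw(24), con)                               # aux_file
  writeBin(c(0L, 1L), con, size = 2)                   # qform_code=0, sform_code=1
  writeBin(numeric(6), con, size = 4)                  # quatern b,c,d + offsets
  writeBin(as.numeric(t(aff[1:3, ])), con, size = 4)   # srow_x/y/z
  writeBin(raw(16), con)                               # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)                                # extension flag
  writeBin(as.numeric(data), con, size = 4)
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' Supports uncompressed single-file `.nii` with int16, float32 or float64
#' data. Returns the data array, the affine and the pixel dimensions.
#'
#' @param path file path.
#' @return list with `data` (3D or 4D array), `affine` (4 x 4), `pixdim`,
#'   `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, integer(), 1, size = 4)
  if (!identical(hdr_size, NIFTI_HDR_SIZE))
    stop_input("malformed NIfTI header in ", path,
               " (sizeof_hdr = ", hdr_size, ", expected 348)")
  invisible(readBin(con, raw(), 36))
  dims <- readBin(con, integer(), 8, size = 2)
  invisible(readBin(con, numeric(), 3, size = 4))
  invisible(readBin(con, integer(), 1, size = 2))
  datatype <- readBin(con, integer(), 1, size = 2)
  invisible(readBin(con, integer(), 1, size = 2))  # bitpix
  invisible(readBin(con, integer(), 1, size = 2))  # slice_start
  pixdim <- readBin(con, numeric(), 8, size = 4)
  vox_offset <- readBin(con, numeric(), 1, size = 4)
  seek(con, 280)  # srow_x starts at byte offset 280
  srow <- readBin(con, numeric(), 12, size = 4)
  affine <- rbind(matrix(srow, 3, 4, byrow = TRUE), c(0, 0, 0, 1))
  nd <- dims[1]
  if (nd < 3 || nd > 4) stop_input("unsupported dimensionality: ", nd)
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  seek(con, vox_offset)
  vals <- switch(as.character(datatype),
                 "4" = readBin(con, integer(), n, size = 2),
                 "16" = readBin(con, numeric(), n, size = 4),
                 "64" = readBin(con, numeric(), n, size = 8),
                 stop_input("unsupported NIfTI datatype: ", datatype))
  if (length(vals) < n)
    stop_input("truncated NIfTI file: expected ", n, " voxels, read ",
               length(vals))
  list(data = array(as.numeric(vals), dim = shape), affine = affine,
       pixdim = pixdim, datatype = datatype)
}

#' Read a 4D NIfTI as a BOLD run
#'
#' @param path `.nii` file written by [write_nifti()] (or compatible).
#' @param design the run's [block_design()].
#' @param motion optional T x 6 motion table.
#' @return a [bold_run()].
#' @export
read_bold <- function(path, design, motion = NULL) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 4) stop_input("expected a 4D BOLD file")
  d <- dim(nii$data)
  spec <- acquisition_spec(tr_seconds = nii$pixdim[5],
                           n_volumes = d[4], grid_shape = d[1:3],
                           voxel_size_mm = nii$pixdim[2])
  bold_run(nii$data, spec, design, motion = motion)
}
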