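# Minimal NIfTI-1 I/O (single-file .nii, little-endian, no compression).
# Only what map/archive output needs: 2-D/3-D arrays, float32/float64/int16.
# No R NIfTI package is available in the target environment, so this is
# deliberately small and self-contained.

NIFTI_DT <- list(int16 = 4L, float32 = 16L, float64 = 64L)
NIFTI_BPP <- c(`4` = 2L, `16` = 4L, `64` = 8L)

#' Write an array to a NIfTI-1 file
#'
#' @param x numeric 2-D or 3-D array. Time/frame axis, if any, must be the
#'   FIRST axis of `x` (package convention); it is stored as the NIfTI
#'   3rd dimension so rows/cols map to the in-plane axes.
#' @param path output `.nii` path.
#' @param datatype `"float64"` (default, lossless for R doubles), `"float32"`
#'   or `"int16"`.
#' @param pixdim numeric voxel dimensions (per stored axis), recycled.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, datatype = c("float64", "float32", "int16"),
                        pixdim = 1) {
  datatype <- match.arg(datatype)
  dt <- NIFTI_DT[[datatype]]
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% 2:3))
    pq_error("pq_io", "write_nifti expects a 2-D or 3-D array")
  # store [rows, cols(, time)]: move a leading time axis last
  if (length(d) == 3L) {
    x <- aperm(x, c(2, 3, 1))
    d <- dim(x)
  }
  ndim <- length(d)
  dims <- integer(8); dims[1] <- ndim; dims[2:(1 + ndim)] <- d
  dims[dims == 0L] <- 1L
  pd <- numeric(8); pd[2:(1 + ndim)] <- rep_len(pixdim, ndim)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # unused fields
  writeBin(as.integer(dims), con, size = 2)           # dim[8]
  writeBin(raw(14), con)                              # intent_p1..3, intent_code
  writeBin(as.integer(c(dt, 8L * NIFTI_BPP[[as.character(dt)]])), con, size = 2)
  writeBin(0L, con, size = 2)                         # slice_start
  writeBin(pd, con, size = 4)                         # pixdim[8]
  writeBin(352, con, size = 4)                        # vox_offset (float)
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(raw(4), con)                               # slice_end(2), slice_code, xyzt_units
  writeBin(numeric(3), con, size = 4)                 # cal_max, cal_min, slice_duration
  writeBin(numeric(1), con, size = 4)                 # toffset
  writeBin(raw(8), con)                               # glmax, glmin
  writeBin(raw(104), con)                             # descrip(80) + aux_file(24)
  writeBin(raw(4), con)                               # qform_code, sform_code
  writeBin(numeric(18), con, size = 4)                # quatern/qoffset/srow
  writeBin(raw(16), con)                              # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)                               # magic terminator
  writeBin(raw(4), con)                               # extension flag
  vals <- as.vector(x)
  if (datatype == "int16") {
    writeBin(as.integer(round(vals)), con, size = 2)
  } else {
    writeBin(as.numeric(vals), con,
             size = NIFTI_BPP[[as.character(dt)]])
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' Returns the array with the package's axis convention (a 3rd stored
#' dimension comes back as the leading time axis).
#'
#' @param path a `.nii` file.
#' @return numeric array.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) pq_error("pq_io", sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (!identical(hdr_size, 348L))
    pq_error("pq_io", "not a little-endian NIfTI-1 file")
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2)
  seek(con, 70)
  dt <- readBin(con, "integer", 1, size = 2)
  seek(con, 108)
  vox_offset <- readBin(con, "double", 1, size = 4)
  ndim <- dims[1]
  d <- dims[2:(1 + ndim)]
  n <- prod(d)
  seek(con, vox_offset)
  vals <- switch(as.character(dt),
    `4`  = readBin(con, "integer", n, size = 2),
    `16` = readBin(con, "double",  n, size = 4),
    `64` = readBin(con, "double",  n, size = 8),
    pq_error("pq_io", sprintf("unsupported NIfTI datatype %d", dt)))
  x <- array(as.numeric(vals), dim = d)
  if (ndim == 3L) x <- aperm(x, c(3, 1, 2))
  x
}
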