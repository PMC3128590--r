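# Minimal single-file NIfTI-1 (.nii / .nii.gz) reader and writer.
#
# The R stack this package targets ships no NIfTI package, so we carry our
# own, restricted to what scalar/4-D diffusion volumes need: dim, datatype,
# bitpix, pixdim, vox_offset, scl_slope/scl_inter and the "n+1" magic.
# Orientation metadata (qform/sform) is written as an identity transform
# scaled by the voxel size and is ignored on read.

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

.nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 image
#'
#' Reads a single-file `.nii` or `.nii.gz` volume into an array. Handles
#' both byte orders and the common integer and float datatypes; applies
#' `scl_slope`/`scl_inter` rescaling when present.
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @return a list with `data` (numeric array with the image dimensions) and
#'   `pixdim` (voxel size per spatial dimension, mm)
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- .nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)

  rd <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size,
            endian = endian)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path)
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI not supported: ", path)

  dim_field <- rd(40L, "integer", 8L, 2L, endian)
  ndim <- dim_field[1L]
  if (ndim < 1L || ndim > 7L) stop("bad ndim in NIfTI header: ", ndim)
  dims <- dim_field[2L:(1L + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L, endian)
  pixdim <- rd(76L, "double", 8L, 4L, endian)
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)

  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = dims),
       pixdim = pixdim[2L:(1L + min(ndim, 3L))])
}

#' Write a NIfTI-1 image
#'
#' Writes an array as a little-endian single-file `.nii` (gzipped when the
#' path ends in `.gz`). `float64` preserves doubles bit-exactly, which the
#' read/write round-trip contract relies on.
#'
#' @param data numeric array, 1-7 dimensions
#' @param path output path ending in `.nii` or `.nii.gz`
#' @param pixdim voxel size per spatial axis, mm (recycled to 3)
#' @param datatype `"float64"`, `"float32"` or `"int32"`
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1),
                        datatype = c("float64", "float32", "int32")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  if (length(dims) > 7L) stop("NIfTI supports at most 7 dimensions")
  if (prod(dims) == 0L) stop("refusing to write an empty (0-voxel) image")
  code <- switch(datatype, float64 = 64L, float32 = 16L, int32 = 8L)
  bitpix <- switch(datatype, float64 = 64L, float32 = 32L, int32 = 32L)
  pixdim <- rep_len(as.double(pixdim), 3L)

  con <- .nii_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4L) writeBin(as.double(x), con, size = size,
                                        endian = "little")
  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  dim_field <- c(length(dims), dims, rep(1L, 7L - length(dims)))
  wi(dim_field, 2L)                              # dim[8]
  wf(c(0, 0, 0))                                 # intent_p1..p3
  wi(0L, 2L)                                     # intent_code
  wi(code, 2L); wi(bitpix, 2L); wi(0L, 2L)       # datatype, bitpix, slice_start
  wf(c(1, pixdim, rep(1, 7L - 3L)))              # pixdim[8] (qfac = 1)
  wf(352)                                        # vox_offset
  wf(1); wf(0)                                   # scl_slope, scl_inter
  wi(0L, 2L); writeBin(raw(2L), con)             # slice_end, slice_code+xyzt
  wf(c(0, 0, 0))                                 # cal_max, cal_min, slice_dur
  wf(0); wi(c(0L, 0L), 4L)                       # toffset, glmax, glmin
  writeBin(raw(104L), con)                       # descrip[80] + aux_file[24]
  wi(c(0L, 1L), 2L)                              # qform_code=0, sform_code=1
  wf(rep(0, 6))                                  # quaternions + offsets
  wf(c(pixdim[1L], 0, 0, 0))                     # srow_x
  wf(c(0, pixdim[2L], 0, 0))                     # srow_y
  wf(c(0, 0, pixdim[3L], 0))                     # srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extender
  if (datatype == "int32") {
    wi(as.vector(data), 4L)
  } else {
    wf(as.vector(data), size = if (datatype == "float64") 8L else 4L)
  }
  invisible(path)
}
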