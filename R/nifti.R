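# Minimal NIfTI-1 input/output.
#
# No NIfTI reader is available among the package's allowed dependencies, so
# a small single-file (.nii / .nii.gz) implementation of the NIfTI-1 format
# is provided here. It covers what gray-matter maps and integer atlases
# need: 3-D volumes, the common datatypes, scl_slope/scl_inter scaling and
# both endiannesses. It is not a general NIfTI library (no extensions,
# no .hdr/.img pairs, no NIfTI-2).

.NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8, signed = TRUE)    # float64
)

.nifti_connection <- function(path, open) {
  con <- gzfile(path, open)  # transparently handles plain and gzipped
  con
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an array,
#' applying `scl_slope`/`scl_inter` scaling when set.
#'
#' @param path file path.
#' @return numeric array with attribute `pixdim` (voxel sizes).
#' @export
read_nifti <- function(path) {
  con <- .nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348)
  if (length(hdr_raw) < 348) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sz <- readBin(hdr_raw, "integer", n = 1, size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw, "integer", n = 1, size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (magic != "n+1") stop("unsupported NIfTI magic '", magic,
                           "' (only single-file n+1 supported)")
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):length(hdr_raw)], what, n = n, size = size,
            endian = endian)
  }
  dim8 <- rd(40, "integer", 8, 2)
  ndim <- dim8[1]
  if (ndim < 1 || ndim > 7) stop("bad NIfTI dim[0]: ", ndim)
  dims <- dim8[2:(1 + ndim)]
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  dt <- .NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n_vox) stop("truncated NIfTI data in ", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr <- array(vals, dim = dims)
  attr(arr, "pixdim") <- pixdim[2:(1 + ndim)]
  arr
}

#' Write a NIfTI-1 volume
#'
#' Writes an array as a single-file NIfTI-1 image. Gray-matter maps are
#' stored as 32-bit floats, integer atlases as 16-bit integers.
#'
#' @param vol numeric or integer array (up to 7-D; typically 3-D).
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param datatype `"float32"`, `"float64"`, `"int16"`, `"int32"` or
#'   `"uint8"`.
#' @param pixdim voxel sizes, recycled to the array rank.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = "float32", pixdim = 1) {
  codes <- c(float32 = 16L, float64 = 64L, int16 = 4L, int32 = 8L,
             uint8 = 2L)
  if (!datatype %in% names(codes)) {
    stop("unsupported datatype: ", datatype)
  }
  code <- codes[[datatype]]
  dt <- .NIFTI_DTYPES[[as.character(code)]]
  dims <- dim(vol)
  if (is.null(dims)) dims <- length(vol)
  ndim <- length(dims)
  if (ndim > 7) stop("arrays beyond 7-D are not valid NIfTI")
  pixdim <- rep_len(pixdim, ndim)

  hdr <- raw(348)
  put <- function(hdr, off, x, what, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0, 348L, "integer", 4)
  dim8 <- as.integer(c(ndim, dims, rep(1L, 7 - ndim)))
  hdr <- put(hdr, 40, dim8, "integer", 2)
  hdr <- put(hdr, 70, code, "integer", 2)
  hdr <- put(hdr, 72, as.integer(dt$size * 8), "integer", 2)
  hdr <- put(hdr, 76, c(1, pixdim, rep(1, 7 - ndim)), "double", 4)
  hdr <- put(hdr, 108, 352, "double", 4)         # vox_offset
  hdr <- put(hdr, 112, c(1, 0), "double", 4)     # scl_slope, scl_inter
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)  # pad to vox_offset = 352
  vals <- as.vector(vol)
  if (dt$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
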