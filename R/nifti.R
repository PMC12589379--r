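# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Scope: 3D/4D volumes on a regular grid with voxel spacing carried in
# pixdim; orientation is pass-through (diagonal sform written, qform 0).
# Supported on read: uint8, int8, int16, uint16, int32, float32, float64,
# little or big endian, scl_slope/scl_inter rescaling. Written as float64
# (images) or int16/int32 (label volumes).

.nii_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.nii_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an R
#' array. Only the fields this package needs are interpreted: dimensions,
#' voxel spacing (pixdim) and value scaling (scl_slope / scl_inter).
#' Orientation metadata is passed over, matching the package-wide assumption
#' that all inputs live on one common grid.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array of 3 or 4 dimensions)
#'   and `spacing_mm` (numeric length-3 voxel edge lengths).
#' @seealso [write_nifti()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("petref: file not found: ", path)
  con <- .nii_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("petref: truncated NIfTI header: ", path)
  rd <- function(offset, what, n, size) {
    readBin(hdr_raw[(offset + 1L):(offset + n * size)], what,
            n = n, size = size, endian = .nii_endian)
  }
  .nii_endian <- "little"
  if (rd(0L, "integer", 1L, 4L) != 348L) {
    .nii_endian <- "big"
    if (rd(0L, "integer", 1L, 4L) != 348L)
      stop("petref: not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("petref: not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1")
    stop("petref: two-file (.hdr/.img) NIfTI is not supported: ", path)
  dim16 <- rd(40L, "integer", 8L, 2L)
  ndim <- dim16[1]
  if (!ndim %in% c(3L, 4L))
    stop("petref: only 3D/4D NIfTI supported, got ndim=", ndim)
  dims <- dim16[2:(1 + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L)
  spec <- .nii_datatypes[[as.character(datatype)]]
  if (is.null(spec)) stop("petref: unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n_vox <- prod(dims)
  vals <- readBin(con, spec$what, n = n_vox, size = spec$size,
                  signed = spec$signed, endian = .nii_endian)
  if (length(vals) != n_vox)
    stop("petref: NIfTI data shorter than header dimensions: ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims),
       spacing_mm = abs(pixdim[2:4]))
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D or 4D array as a single-file NIfTI-1 image. Values are stored
#' as float64 unless `datatype = "int16"` or `"int32"` is requested (used
#' for label atlases). A diagonal sform encoding the voxel spacing is
#' written; gzip compression follows the file extension.
#'
#' @param data Numeric or integer array with 3 or 4 dimensions.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing_mm Voxel edge lengths in mm (length 3).
#' @param datatype `"float64"` (default), `"int32"` or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing_mm = c(1, 1, 1),
                        datatype = c("float64", "int32", "int16")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims) || !length(dims) %in% c(3L, 4L))
    stop("petref: write_nifti expects a 3D or 4D array")
  if (any(!is.finite(data))) stop("petref: non-finite values in image data")
  dt_code <- switch(datatype, float64 = 64L, int32 = 8L, int16 = 4L)
  bitpix <- switch(datatype, float64 = 64L, int32 = 32L, int16 = 16L)
  con <- .nii_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type, db_name, extents, session_error, regular, dim_info
  dim16 <- rep(1L, 8L)
  dim16[1] <- length(dims)
  dim16[2:(1 + length(dims))] <- dims
  w_i16(dim16)                      # dim
  w_f32(c(0, 0, 0))                 # intent_p1..3
  w_i16(c(0L, dt_code, bitpix, 0L)) # intent_code, datatype, bitpix, slice_start
  pixdim <- c(1, spacing_mm, 1, 1, 1, 1)
  w_f32(pixdim)                     # pixdim (qfac = 1)
  w_f32(352)                        # vox_offset
  w_f32(c(1, 0))                    # scl_slope, scl_inter
  w_i16(0L)                         # slice_end
  writeBin(as.raw(c(0L, 10L)), con) # slice_code, xyzt_units (mm | s)
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(104L)                       # descrip, aux_file
  w_i16(c(0L, 1L))                  # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                  # quatern_b/c/d, qoffset_x/y/z
  w_f32(c(spacing_mm[1], 0, 0, 0))  # srow_x
  w_f32(c(0, spacing_mm[2], 0, 0))  # srow_y
  w_f32(c(0, 0, spacing_mm[3], 0))  # srow_z
  w_raw(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                         # extender
  if (datatype == "float64") {
    writeBin(as.double(data), con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(data), con, size = bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}
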