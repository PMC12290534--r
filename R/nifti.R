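# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# The package operates strictly in one common space, so only the header
# fields it actually uses are interpreted: dim, datatype/bitpix, pixdim
# (voxel spacing), vox_offset, scl_slope/scl_inter, and descrip (which
# carries the space tag). Orientation (qform/sform) is written as a plain
# scaled-identity affine and never used for resampling decisions.

NIFTI_HDR_SIZE <- 348L

nifti_open_read <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  # gzfile transparently reads both plain and gzip-compressed streams
  gzfile(path, "rb")
}

nifti_read_header <- function(con) {
  raw_hdr <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(raw_hdr) < NIFTI_HDR_SIZE)
    stop("read_volume: truncated NIfTI header")
  endian <- "little"
  sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L)
      stop("read_volume: not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(raw_hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("read_volume: bad NIfTI magic '", magic, "'")
  if (magic == "ni1")
    stop("read_volume: two-file (.hdr/.img) NIfTI pairs are not supported")
  dim <- rd(40, "integer", 8, 2)
  datatype <- rd(70, "integer", 1, 2)
  bitpix <- rd(72, "integer", 1, 2)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  descrip_raw <- raw_hdr[149:228]
  nz <- which(descrip_raw == as.raw(0))
  descrip <- rawToChar(descrip_raw[seq_len(if (length(nz)) nz[1] - 1 else 80)])
  list(endian = endian, dim = dim, datatype = datatype, bitpix = bitpix,
       pixdim = pixdim, vox_offset = vox_offset,
       scl_slope = scl_slope, scl_inter = scl_inter, descrip = descrip)
}

nifti_read_data <- function(con, hdr) {
  ndim <- hdr$dim[1]
  shape <- hdr$dim[2:(1 + max(ndim, 1))]
  if (ndim > 3L) {
    if (any(shape[4:ndim] != 1L))
      stop("read_volume: ", ndim, "D input; only 3D volumes are supported")
    shape <- shape[1:3]
  }
  if (length(shape) != 3L || any(shape < 1L))
    stop("read_volume: only 3D volumes are supported (dim[0] = ", ndim, ")")
  skip <- as.integer(round(hdr$vox_offset)) - NIFTI_HDR_SIZE
  if (skip > 0L) invisible(readBin(con, "raw", n = skip))
  nvox <- prod(shape)
  vals <- switch(as.character(hdr$datatype),
    "2"   = readBin(con, "integer", n = nvox, size = 1, signed = FALSE,
                    endian = hdr$endian),
    "4"   = readBin(con, "integer", n = nvox, size = 2, signed = TRUE,
                    endian = hdr$endian),
    "8"   = readBin(con, "integer", n = nvox, size = 4, endian = hdr$endian),
    "16"  = readBin(con, "numeric", n = nvox, size = 4, endian = hdr$endian),
    "64"  = readBin(con, "numeric", n = nvox, size = 8, endian = hdr$endian),
    "512" = readBin(con, "integer", n = nvox, size = 2, signed = FALSE,
                    endian = hdr$endian),
    stop("read_volume: unsupported NIfTI datatype code ", hdr$datatype))
  if (length(vals) != nvox)
    stop("read_volume: truncated NIfTI data section")
  vals <- as.double(vals)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0))
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  array(vals, dim = shape)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into a
#' [volume()]. Voxel spacing is taken from `pixdim`; the `descrip` field, if
#' set, becomes the space tag. Non-finite voxels are rejected with an error
#' naming how many are affected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An `spc_volume`.
#' @export
read_volume <- function(path) {
  con <- nifti_open_read(path)
  on.exit(close(con))
  hdr <- nifti_read_header(con)
  data <- nifti_read_data(con, hdr)
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stop("read_volume: ", path, " contains ", nbad, " non-finite voxel(s)")
  spacing <- hdr$pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("read_volume: invalid voxel spacing in header: (",
         paste(spacing, collapse = ", "), ")")
  volume(data, spacing = spacing,
         space_tag = if (nzchar(hdr$descrip)) hdr$descrip else "unspecified")
}

#' Read a 3D NIfTI-1 label map
#'
#' As [read_volume()] but validates that all values are non-negative
#' integers and returns a [label_volume()].
#'
#' @inheritParams read_volume
#' @param label_names optional label-id-to-name map attached to the result.
#' @return An `spc_labels`.
#' @export
read_label_volume <- function(path, label_names = NULL) {
  v <- read_volume(path)
  if (any(v$data < 0) || max(abs(v$data - round(v$data))) > 0)
    stop("read_label_volume: ", path, " contains non-integer or negative values")
  label_volume(array(as.integer(round(v$data)), dim = v$shape),
               spacing = v$spacing, space_tag = v$space_tag,
               label_names = label_names)
}

nifti_write <- function(arr, spacing, space_tag, path, datatype) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_volume: directory does not exist: ", dir)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_chr <- function(s, n) {
    r <- charToRaw(substr(s, 1, n - 1))
    writeBin(c(r, rep(as.raw(0), n - length(r))), con)
  }
  bitpix <- if (datatype == 16L) 32L else 16L
  shape <- dim(arr)
  w_i32(348)                                   # sizeof_hdr
  w_chr("", 10); w_chr("", 18)                 # data_type, db_name
  w_i32(0); w_i16(0); writeBin(as.raw(c(114, 0)), con)  # extents, session_error, regular 'r', dim_info
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L))          # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)                  # intent_p1..p3, intent_code
  w_i16(datatype); w_i16(bitpix); w_i16(0)     # datatype, bitpix, slice_start
  w_f32(c(1, spacing, 1, 1, 1, 1))             # pixdim[8], qfac = 1
  w_f32(352)                                   # vox_offset
  w_f32(1); w_f32(0)                           # scl_slope, scl_inter
  w_i16(0); writeBin(as.raw(c(0, 10)), con)    # slice_end, slice_code, xyzt_units (mm|s)
  w_f32(c(0, 0, 0, 0))                         # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0, 0))                               # glmax, glmin
  w_chr(space_tag, 80)                         # descrip carries the space tag
  w_chr("", 24)                                # aux_file
  w_i16(0); w_i16(1)                           # qform_code = 0, sform_code = 1
  w_f32(c(0, 0, 0)); w_f32(c(0, 0, 0))         # quaternion, qoffset
  w_f32(c(spacing[1], 0, 0, 0))                # srow_x
  w_f32(c(0, spacing[2], 0, 0))                # srow_y
  w_f32(c(0, 0, spacing[3], 0))                # srow_z
  w_chr("", 16)                                # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(as.raw(c(0, 0, 0, 0)), con)         # extension indicator
  if (datatype == 16L) w_f32(as.vector(arr)) else w_i16(as.vector(arr))
  invisible(path)
}

#' Write a volume or label map as NIfTI-1
#'
#' Intensities are written as 32-bit floats, labels as 16-bit integers
#' (matching the dynamic range after 0-1000 normalization). The space tag is
#' stored in the header `descrip` field so it round-trips.
#'
#' @param vol an `spc_volume` or `spc_labels`.
#' @param path output path ending in `.nii` or `.nii.gz`; parent directory
#'   must exist.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (is_volume(vol)) {
    nifti_write(vol$data, vol$spacing, vol$space_tag, path, datatype = 16L)
  } else if (is_labels(vol)) {
    if (max(vol$labels) > 32767L)
      stop("write_volume: label ids exceed the int16 on-disk range")
    nifti_write(vol$labels, vol$spacing, vol$space_tag, path, datatype = 4L)
  } else {
    stop("write_volume: expected an spc_volume or spc_labels object")
  }
}
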