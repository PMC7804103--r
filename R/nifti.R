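#' Minimal NIfTI-1 I/O
#'
#' Self-contained reader/writer for single-file NIfTI-1 (`.nii`, `.nii.gz`)
#' supporting 3D and 4D volumes. Voxel spacing is carried in `pixdim` and the
#' origin in the `qoffset` fields (qform code 1, identity rotation). Volumes
#' are written as float32. This covers the package's own outputs and typical
#' scanner exports with datatypes uint8/int16/int32/uint16/float32/float64;
#' it is not a general-purpose NIfTI library (no slope/intercept scaling
#' other than applying `scl_slope`/`scl_inter`, no oblique orientations).
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_nifti()` returns a [volume3d] for 3D files, or a list
#'   `list(values = 4D array, spacing_mm, origin_mm, dt)` for 4D files.
#' @name nifti_io
NULL

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' @rdname nifti_io
#' @param vol a [volume3d], or a 4D numeric array for time series.
#' @param spacing_mm,origin_mm used when `vol` is a bare array.
#' @param dt time step (s), stored in `pixdim[5]` for 4D data.
#' @export
write_nifti <- function(vol, path, spacing_mm = NULL, origin_mm = NULL,
                        dt = 1) {
  if (is_volume3d(vol)) {
    values <- vol$values
    spacing_mm <- vol$spacing_mm
    origin_mm <- vol$origin_mm
  } else {
    values <- as.array(vol)
    if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
    if (is.null(origin_mm)) origin_mm <- c(0, 0, 0)
  }
  nd <- length(dim(values))
  if (!nd %in% c(3L, 4L)) stop("only 3D/4D volumes supported", call. = FALSE)
  d <- dim(values)
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348L, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)            # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2); wc("", 1); wc("", 1)  # extents, session_error, regular, dim_info
  dimv <- c(nd, d, rep(1L, 7 - nd))
  wi(dimv, 2)                       # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..p3
  wi(0L, 2)                         # intent_code
  wi(16L, 2)                        # datatype = float32
  wi(32L, 2)                        # bitpix
  wi(0L, 2)                         # slice_start
  wf(c(1, spacing_mm, if (nd == 4) dt else 1, 1, 1, 1)[1:8])  # pixdim[8]
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2); wc("", 1)              # slice_end, slice_code
  wc(rawToChar(as.raw(10L)), 1)     # xyzt_units: mm (2) + sec (8) = 10
  wf(0); wf(0)                      # cal_max, cal_min
  wf(0); wf(0)                      # slice_duration, toffset
  wi(0L, 4); wi(0L, 4)              # glmax, glmin (unused)
  wc("resectquant", 80)             # descrip
  wc("", 24)                        # aux_file
  wi(1L, 2); wi(0L, 2)              # qform_code = 1, sform_code = 0
  wf(c(0, 0, 0))                    # quatern b, c, d (identity)
  wf(origin_mm)                     # qoffset x, y, z
  wf(rep(0, 12))                    # srow_x/y/z (unused, sform 0)
  wc("", 16)                        # intent_name
  wc("n+1", 4)                      # magic
  writeBin(raw(4), con)             # extension flag
  wf(as.numeric(values))
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  rd <- function(what, n, size, offset, endian) {
    readBin(hdr[(offset + 1):length(hdr)], what, n = n, size = size,
            endian = endian)
  }
  endian <- "little"
  if (rd("integer", 1, 4, 0, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1, 4, 0, endian) != 348L)
      stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  dimv <- rd("integer", 8, 2, 40, endian)
  nd <- dimv[1]
  if (!nd %in% c(3L, 4L))
    stop("only 3D/4D NIfTI supported (got ", nd, "D)", call. = FALSE)
  d <- dimv[2:(1 + nd)]
  datatype <- rd("integer", 1, 2, 70, endian)
  pixdim <- rd("numeric", 8, 4, 76, endian)
  vox_offset <- rd("numeric", 1, 4, 108, endian)
  scl_slope <- rd("numeric", 1, 4, 112, endian)
  scl_inter <- rd("numeric", 1, 4, 116, endian)
  qoffset <- rd("numeric", 3, 4, 268, endian)
  n <- prod(d)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  values <- switch(as.character(datatype),
    "2"   = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4"   = as.numeric(readBin(con, "integer", n, size = 2, endian = endian)),
    "8"   = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    "16"  = readBin(con, "numeric", n, size = 4, endian = endian),
    "64"  = readBin(con, "numeric", n, size = 8, endian = endian),
    "512" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                               endian = endian)),
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE))
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    values <- values * scl_slope + scl_inter
  arr <- array(values, dim = d)
  spacing <- pixdim[2:4]
  if (nd == 3L) {
    volume3d(arr, spacing_mm = spacing, origin_mm = qoffset)
  } else {
    list(values = arr, spacing_mm = spacing, origin_mm = qoffset,
         dt = pixdim[5])
  }
}
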