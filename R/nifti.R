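# Minimal NIfTI-1/2 I/O. No NIfTI package is assumed; the format is read and
# written directly. Only the fields the QC metrics consume are interpreted:
# dims, pixdim (voxel size + TR), datatype, scl_slope/inter, xyzt time units.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_int64 <- function(con, n, endian) {
  # dims/offsets are far below 2^53; combine two 32-bit words
  words <- readBin(con, "integer", n = 2L * n, size = 4L, endian = endian)
  lo_first <- endian == "little"
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- words[2 * i - 1]; b <- words[2 * i]
    lo <- if (lo_first) a else b
    hi <- if (lo_first) b else a
    if (lo < 0) lo <- lo + 2^32
    out[i] <- hi * 2^32 + lo
  }
  out
}

# Parse a NIfTI-1 or NIfTI-2 header; returns dims, pixdim, datatype,
# vox_offset, scl_slope/inter, time unit code.
read_nifti_header <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  endian <- "little"
  if (!first %in% c(348L, 540L)) {
    # try big-endian
    close(con); on.exit()
    con <- nifti_open(path, "rb")
    on.exit(close(con))
    first <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    endian <- "big"
    if (!first %in% c(348L, 540L))
      stop("not a NIfTI file (unrecognised header size): ", path)
  }
  if (first == 348L) {                                  # NIfTI-1
    readBin(con, "raw", n = 36L)                        # skip to offset 40
    dims <- readBin(con, "integer", n = 8L, size = 2L, endian = endian)
    readBin(con, "raw", n = 14L)                        # intent_p1..3, intent_code
    datatype <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
    bitpix <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
    readBin(con, "raw", n = 2L)                         # slice_start
    pixdim <- readBin(con, "numeric", n = 8L, size = 4L, endian = endian)
    vox_offset <- readBin(con, "numeric", n = 1L, size = 4L, endian = endian)
    scl_slope <- readBin(con, "numeric", n = 1L, size = 4L, endian = endian)
    scl_inter <- readBin(con, "numeric", n = 1L, size = 4L, endian = endian)
    readBin(con, "raw", n = 3L)                         # slice_end, slice_code
    xyzt <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
  } else {                                              # NIfTI-2
    readBin(con, "raw", n = 8L)                         # magic
    datatype <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
    bitpix <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
    dims <- read_int64(con, 8L, endian)
    readBin(con, "raw", n = 24L)                        # intent_p1..3
    pixdim <- readBin(con, "numeric", n = 8L, size = 8L, endian = endian)
    vox_offset <- read_int64(con, 1L, endian)
    scl_slope <- readBin(con, "numeric", n = 1L, size = 8L, endian = endian)
    scl_inter <- readBin(con, "numeric", n = 1L, size = 8L, endian = endian)
    readBin(con, "raw", n = 308L)                       # through slice_code
    xyzt <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
  }
  list(dims = dims, datatype = datatype, bitpix = bitpix, pixdim = pixdim,
       vox_offset = vox_offset, scl_slope = scl_slope, scl_inter = scl_inter,
       xyzt_units = xyzt, endian = endian, nifti_version = if (first == 348L) 1L else 2L)
}

read_nifti_data <- function(path, hdr) {
  dt <- NIFTI_DTYPES[[as.character(hdr$datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", hdr$datatype, " in ", path)
  ndim <- hdr$dims[1]
  sizes <- hdr$dims[2:(1 + ndim)]
  n <- prod(sizes)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = hdr$vox_offset)
  x <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = hdr$endian)
  if (length(x) != n)
    stop("truncated NIfTI data in ", path, ": expected ", n,
         " voxels, read ", length(x))
  x <- as.numeric(x)
  sl <- hdr$scl_slope; ic <- hdr$scl_inter
  if (is.finite(sl) && sl != 0 && !(sl == 1 && ic == 0))
    x <- x * sl + ic
  array(x, dim = sizes)
}

# drop trailing singleton dimensions (e.g. a 64x64x30x1 "4D" file is 3D)
collapse_singletons <- function(sizes) {
  while (length(sizes) > 3L && sizes[length(sizes)] == 1L)
    sizes <- sizes[-length(sizes)]
  sizes
}

time_unit_scale <- function(xyzt) {
  switch(as.character(bitwAnd(as.integer(xyzt), 56L)),
         `8` = 1, `16` = 1e-3, `24` = 1e-6, 1)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 or NIfTI-2 file (optionally gzipped) with three spatial
#' dimensions into a [qc_volume]. Voxel sizes come from the header `pixdim`;
#' intensities are returned unchanged apart from the header's
#' `scl_slope`/`scl_inter` scaling. Non-finite voxels are a load error.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param slice_axis acquisition slice axis (default 3, the stored
#'   third axis).
#' @return a [qc_volume].
#' @export
read_volume <- function(path, slice_axis = 3L) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  hdr <- read_nifti_header(path)
  sizes <- collapse_singletons(hdr$dims[2:(1 + hdr$dims[1])])
  if (length(sizes) != 3L)
    stop("expected a 3D volume but ", path, " has ", length(sizes),
         " non-singleton dimensions")
  vals <- read_nifti_data(path, hdr)
  dim(vals) <- sizes
  qc_volume(vals, voxel_size = hdr$pixdim[2:4], slice_axis = slice_axis)
}

#' Read a 4D NIfTI series
#'
#' @param path file path to a NIfTI file with a 4th dimension of at least 2.
#' @param slice_axis acquisition slice axis (default 3).
#' @return a [qc_series]; `frame_interval` is taken from the header timing
#'   field (`pixdim[4]`, converted to seconds) when positive.
#' @export
read_series <- function(path, slice_axis = 3L) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  hdr <- read_nifti_header(path)
  sizes <- collapse_singletons(hdr$dims[2:(1 + hdr$dims[1])])
  if (length(sizes) < 4L)
    stop("series requires >= 2 frames; ", path, " is a 3D volume")
  if (length(sizes) > 4L)
    stop("more than 4 non-singleton dimensions in ", path)
  vals <- read_nifti_data(path, hdr)
  dim(vals) <- sizes
  tr <- hdr$pixdim[5] * time_unit_scale(hdr$xyzt_units)
  qc_series(vals, voxel_size = hdr$pixdim[2:4],
            frame_interval = if (is.finite(tr) && tr > 0) tr else NULL,
            slice_axis = slice_axis)
}

#' Read a binary mask volume
#'
#' @param path NIfTI file containing 0/1 values.
#' @return logical 3D array.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  u <- unique(as.vector(vol$values))
  if (!all(u %in% c(0, 1)))
    stop("mask file ", path, " is not binary (values other than 0/1 present)")
  vol$values > 0.5
}

dtype_code <- function(datatype) {
  switch(datatype,
         uint8 = c(2L, 8L), int16 = c(4L, 16L), int32 = c(8L, 32L),
         float32 = c(16L, 32L), float64 = c(64L, 64L),
         stop("unsupported write datatype: ", datatype))
}

write_nifti <- function(values, voxel_size, path, datatype, tr = NULL) {
  sizes <- dim(values)
  ndim <- length(sizes)
  dims <- integer(8); dims[1] <- ndim; dims[2:(1 + ndim)] <- sizes
  if (ndim < 7) dims[(2 + ndim):8] <- 1L
  pixdim <- numeric(8)
  pixdim[2:4] <- voxel_size
  pixdim[5] <- if (!is.null(tr)) tr else 0
  dc <- dtype_code(datatype)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4L)                                  # sizeof_hdr
  writeBin(raw(36L), con)                       # data_type..dim_info
  wi(dims, 2L)                                  # dim[8]
  writeBin(raw(14L), con)                       # intent_p*, intent_code
  wi(dc[1], 2L); wi(dc[2], 2L)                  # datatype, bitpix
  wi(0L, 2L)                                    # slice_start
  wf(pixdim)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2L); writeBin(as.raw(0L), con)         # slice_end, slice_code
  writeBin(as.raw(bitwOr(2L, 8L)), con)         # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(c(0L, 0L), 4L)                             # glmax, glmin
  writeBin(raw(80L + 24L), con)                 # descrip, aux_file
  wi(c(0L, 1L), 2L)                             # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern, qoffset
  wf(c(voxel_size[1], 0, 0, 0))                 # srow_x
  wf(c(0, voxel_size[2], 0, 0))                 # srow_y
  wf(c(0, 0, voxel_size[3], 0))                 # srow_z
  writeBin(raw(16L), con)                       # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL)
  writeBin(as.raw(0L), con)
  writeBin(raw(4L), con)                        # extension flag
  v <- as.vector(values)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(v)), con, size = dc[2] %/% 8L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = dc[2] %/% 8L, endian = "little")
  }
  invisible(path)
}

#' Write a volume or series to NIfTI-1
#'
#' @param x a [qc_volume] or [qc_series].
#' @param path output path; a `.gz` suffix gzips the file.
#' @param datatype one of `"float32"` (default), `"float64"`, `"int16"`,
#'   `"int32"`, `"uint8"`. Integer types are written by rounding.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, datatype = "float32") {
  if (inherits(x, "qc_series"))
    return(invisible(write_nifti(x$values, x$voxel_size, path, datatype,
                                 tr = x$frame_interval)))
  if (!inherits(x, "qc_volume")) stop("`x` must be a qc_volume or qc_series")
  invisible(write_nifti(x$values, x$voxel_size, path, datatype))
}

#' Read an FSL-dialect gradient table
#'
#' `bvals` is one whitespace-separated row of b-values; `bvecs` is three rows
#' (x, y, z components), one column per frame.
#'
#' @param bval_path path to the b-value file.
#' @param bvec_path path to the b-vector file.
#' @param n_frames optional expected frame count; mismatch is an error.
#' @param b0_tolerance passed to [qc_gradients()].
#' @return a [qc_gradients].
#' @export
read_gradients <- function(bval_path, bvec_path, n_frames = NULL,
                           b0_tolerance = 50) {
  b <- scan(bval_path, quiet = TRUE)
  rows <- utils::read.table(bvec_path)
  if (nrow(rows) != 3L)
    stop("bvec file must have exactly 3 rows, got ", nrow(rows))
  g <- as.matrix(rows)
  dimnames(g) <- NULL
  if (ncol(g) != length(b))
    stop("gradient table mismatch: ", length(b), " b-values but ",
         ncol(g), " bvec columns")
  if (!is.null(n_frames) && length(b) != n_frames)
    stop("gradient table has ", length(b), " entries but the series has ",
         n_frames, " frames")
  qc_gradients(b, g, b0_tolerance = b0_tolerance)
}
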