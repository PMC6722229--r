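#' Image containers
#'
#' `qc_volume` wraps a 3D scalar voxel grid together with the geometric
#' metadata every metric needs: voxel size in mm per axis, the stored-axis to
#' anatomical-axis mapping, and the acquisition slice axis. `qc_series` wraps
#' an ordered set of frames sharing one grid (fMRI time series or DWI
#' gradient series).
#'
#' @name containers
NULL

#' Construct a 3D volume
#'
#' @param values numeric 3D array of voxel intensities. All values must be
#'   finite and every axis must have at least 8 voxels.
#' @param voxel_size numeric length-3, mm per stored axis; strictly positive.
#' @param axis_order character length-3 mapping stored axes to anatomical
#'   axes; purely informational.
#' @param slice_axis integer in 1:3, the acquisition slice dimension.
#' @return object of class `qc_volume`.
#' @export
qc_volume <- function(values, voxel_size = c(1, 1, 1),
                      axis_order = c("x", "y", "z"), slice_axis = 3L) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "double"
  d <- dim(values)
  if (any(d < 8L))
    stop("volume grid must have >= 8 voxels per axis; got ",
         paste(d, collapse = "x"))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three strictly positive finite numbers")
  nbad <- sum(!is.finite(values))
  if (nbad > 0L)
    stop("volume contains ", nbad, " non-finite voxel(s)")
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3")
  structure(
    list(values = values, voxel_size = voxel_size,
         axis_order = axis_order, slice_axis = slice_axis),
    class = "qc_volume")
}

#' @export
print.qc_volume <- function(x, ...) {
  cat("<qc_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm, slice axis ", x$slice_axis, "\n", sep = "")
  invisible(x)
}

#' Construct a 4D series
#'
#' @param values numeric 4D array (x, y, z, frame); at least 2 frames.
#' @param voxel_size numeric length-3, mm per spatial axis.
#' @param frame_interval repetition time in seconds (TR), or `NULL` for
#'   series without a meaningful frame clock (DWI).
#' @param slice_axis acquisition slice dimension (1:3).
#' @return object of class `qc_series`.
#' @export
qc_series <- function(values, voxel_size = c(1, 1, 1), frame_interval = NULL,
                      slice_axis = 3L) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("`values` must be a 4D array")
  storage.mode(values) <- "double"
  d <- dim(values)
  if (d[4] < 2L) stop("series requires >= 2 frames")
  if (any(d[1:3] < 8L))
    stop("series grid must have >= 8 voxels per spatial axis")
  nbad <- sum(!is.finite(values))
  if (nbad > 0L)
    stop("series contains ", nbad, " non-finite voxel(s)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three strictly positive finite numbers")
  if (!is.null(frame_interval)) {
    frame_interval <- as.numeric(frame_interval)
    if (length(frame_interval) != 1L || !is.finite(frame_interval) ||
        frame_interval <= 0)
      stop("`frame_interval` must be a positive scalar (seconds) or NULL")
  }
  structure(
    list(values = values, voxel_size = voxel_size,
         frame_interval = frame_interval, slice_axis = as.integer(slice_axis)),
    class = "qc_series")
}

#' @export
print.qc_series <- function(x, ...) {
  d <- dim(x$values)
  cat("<qc_series> ", d[4], " frames of ", paste(d[1:3], collapse = " x "),
      " voxels", if (!is.null(x$frame_interval))
        paste0(", TR ", x$frame_interval, " s"), "\n", sep = "")
  invisible(x)
}

#' Number of frames in a series
#' @param series a `qc_series`.
#' @export
n_frames <- function(series) dim(series$values)[4]

#' Extract one frame of a series as a `qc_volume`
#' @param series a `qc_series`.
#' @param t frame index (1-based).
#' @export
get_frame <- function(series, t) {
  d <- dim(series$values)
  if (t < 1L || t > d[4]) stop("frame index out of range")
  qc_volume(array(series$values[, , , t], dim = d[1:3]),
            voxel_size = series$voxel_size, slice_axis = series$slice_axis)
}

#' Diffusion gradient scheme
#'
#' Per-frame diffusion weighting: b-values in s/mm^2 and unit gradient
#' directions. At least one frame must be a b=0 reference (b below
#' `b0_tolerance`); for diffusion-weighted frames the direction must have
#' unit norm to within 1e-3.
#'
#' @param b_values numeric vector, one b per frame.
#' @param directions 3 x n matrix of gradient directions (columns = frames).
#' @param b0_tolerance b-values at or below this count as b=0 references
#'   (default 50 s/mm^2, a common scanner convention).
#' @return object of class `qc_gradients`.
#' @export
qc_gradients <- function(b_values, directions, b0_tolerance = 50) {
  b_values <- as.numeric(b_values)
  directions <- as.matrix(directions)
  if (nrow(directions) != 3L)
    stop("`directions` must be a 3 x n matrix (one column per frame)")
  if (ncol(directions) != length(b_values))
    stop("gradient table mismatch: ", length(b_values), " b-values but ",
         ncol(directions), " direction columns")
  if (any(!is.finite(b_values)) || any(b_values < 0))
    stop("b-values must be finite and non-negative")
  if (!any(b_values <= b0_tolerance))
    stop("no b=0 reference volume (no b-value <= ", b0_tolerance, ")")
  dwi <- which(b_values > b0_tolerance)
  if (length(dwi)) {
    nrm <- sqrt(colSums(directions[, dwi, drop = FALSE]^2))
    off <- which(abs(nrm - 1) > 1e-3)
    if (length(off))
      stop("non-unit gradient direction(s) at diffusion-weighted frame(s) ",
           paste(dwi[off], collapse = ", "),
           " (norms ", paste(signif(nrm[off], 4), collapse = ", "), ")")
  }
  structure(
    list(b_values = b_values, directions = directions,
         b0_tolerance = b0_tolerance),
    class = "qc_gradients")
}

#' @export
print.qc_gradients <- function(x, ...) {
  nb0 <- sum(x$b_values <= x$b0_tolerance)
  cat("<qc_gradients> ", length(x$b_values), " frames (", nb0,
      " b=0, max b ", max(x$b_values), " s/mm^2)\n", sep = "")
  invisible(x)
}

# mm coordinates of every voxel centre along one axis (0-based index * size)
axis_mm <- function(n, size) (seq_len(n) - 1) * size

# population SD (divisor N); the package-wide convention for image statistics
sd_pop <- function(x) {
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

var_pop <- function(x) {
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
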