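#' fMRI time-series quality metrics
#'
#' Scalar metrics: framewise displacement (FD) with its maximum and the
#' count of frames above 0.5 mm; DVARS (RMS frame-to-frame BOLD change on a
#' median-1000 intensity scale) with max/min and the count above 50; and
#' average temporal SNR. Plotted quantities: SFNR, per-frame outlier voxel
#' fractions, volume-mean velocity, frequency-spectrum summaries and
#' frame-wise structural descriptors.
#'
#' @name fmri_metrics
NULL

#' Framewise displacement from rigid parameters
#'
#' Power's construction: the absolute frame-to-frame differences of the six
#' rigid parameters are summed, with rotations converted to arc length at a
#' nominal head radius. The first frame's FD is 0 by construction.
#'
#' @param params a `qc_rigid_params` (or an `n x 6` matrix: tx, ty, tz mm,
#'   rx, ry, rz radians).
#' @param head_radius rotation-to-displacement radius in mm (default 50).
#' @param threshold exceedance threshold in mm (default 0.5).
#' @param basis `"frame_to_frame"` (Power, default) or `"first_frame"`
#'   (differences taken against the reference frame's parameters).
#' @return list with `fd` (per-frame vector, mm), `max_fd`, `n_above`
#'   (count of frames with FD > threshold) and `flagged` (frames whose FD
#'   is undefined because a registration failed).
#' @export
framewise_displacement <- function(params, head_radius = 50,
                                   threshold = 0.5,
                                   basis = c("frame_to_frame",
                                             "first_frame")) {
  basis <- match.arg(basis)
  p <- if (inherits(params, "qc_rigid_params")) params$params else params
  p <- as.matrix(p)
  if (ncol(p) != 6L) stop("expected 6 rigid parameters per frame")
  nt <- nrow(p)
  dp <- if (basis == "frame_to_frame") diff(p)
        else sweep(p[-1, , drop = FALSE], 2L, p[1, ], `-`)
  fd <- c(0, rowSums(abs(dp[, 1:3, drop = FALSE])) +
             head_radius * rowSums(abs(dp[, 4:6, drop = FALSE])))
  flagged <- which(!is.finite(fd))
  list(fd = fd, max_fd = max(fd, na.rm = TRUE),
       n_above = sum(fd > threshold, na.rm = TRUE),
       threshold = threshold, flagged = flagged)
}

#' DVARS: RMS frame-to-frame signal change
#'
#' Intensities are first rescaled so that the median within-mask intensity
#' of the temporal mean volume is 1000 (so the default threshold of 50
#' corresponds to a 5% signal change); DVARS at frame t is the root mean
#' square over mask voxels of the intensity change from frame t-1. DVARS at
#' the first frame is 0 by construction and excluded from the minimum.
#'
#' @param series a [qc_series].
#' @param brain_mask logical array.
#' @param normalize apply the median-1000 rescaling (default TRUE).
#' @param threshold exceedance threshold (default 50).
#' @return list with `dvars`, `max_dvars`, `min_dvars`, `n_above`.
#' @export
compute_dvars <- function(series, brain_mask, normalize = TRUE,
                          threshold = 50) {
  d <- dim(series$values)
  if (!identical(dim(brain_mask), d[1:3])) stop("mask grid mismatch")
  idx <- which(brain_mask)
  if (!length(idx)) stop("empty mask")
  nt <- d[4]
  mat <- matrix(series$values, prod(d[1:3]), nt)[idx, , drop = FALSE]
  if (normalize) {
    med <- stats::median(rowMeans(mat))
    if (med == 0) stop("cannot normalize: zero median intensity in mask")
    mat <- mat * (1000 / med)
  }
  dif <- mat[, -1, drop = FALSE] - mat[, -nt, drop = FALSE]
  dvars <- c(0, sqrt(colMeans(dif^2)))
  list(dvars = dvars, max_dvars = max(dvars[-1]),
       min_dvars = min(dvars[-1]),
       n_above = sum(dvars > threshold), threshold = threshold)
}

#' Temporal SNR
#'
#' Per voxel, the temporal mean divided by the temporal SD (sample SD over
#' frames, no detrending). The average is taken over mask voxels with
#' non-zero SD; the number of excluded zero-SD voxels is reported.
#'
#' @param series a [qc_series].
#' @param brain_mask logical array.
#' @return list with `tsnr_map` (3D array, NA outside mask / at zero-SD
#'   voxels), `avg_tsnr`, `n_zero_sd`.
#' @export
temporal_snr <- function(series, brain_mask) {
  d <- dim(series$values)
  idx <- which(brain_mask)
  if (!length(idx)) stop("empty mask")
  if (d[4] < 10L)
    warning("temporal SNR over fewer than 10 frames is unstable")
  mat <- matrix(series$values, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  mu <- rowMeans(mat)
  s <- sqrt(rowSums((mat - mu)^2) / (d[4] - 1L))
  tsnr <- ifelse(s > 0, mu / s, NA_real_)
  map <- array(NA_real_, d[1:3])
  map[idx] <- tsnr
  n_zero <- sum(s == 0)
  avg <- if (all(s == 0)) NA_real_ else mean(tsnr[s > 0])
  list(tsnr_map = map, avg_tsnr = avg, n_zero_sd = n_zero)
}

# residuals after per-voxel second-order polynomial detrend
# mat: voxels x frames
poly2_residuals <- function(mat) {
  nt <- ncol(mat)
  X <- cbind(1, stats::poly(seq_len(nt), degree = 2))
  # residual maker applied from the right: mat %*% (I - H)
  Q <- qr.Q(qr(X))
  mat - (mat %*% Q) %*% t(Q)
}

#' Signal-to-fluctuation-noise ratio
#'
#' Per voxel, the temporal mean divided by the SD of the residuals after a
#' second-order polynomial detrend (the fluctuation noise). Coincides with
#' temporal SNR when no trend is present.
#'
#' @param series a [qc_series] with at least 20 frames.
#' @param brain_mask logical array.
#' @return list with `sfnr_map`, `median_sfnr`, `n_zero_sd`.
#' @export
compute_sfnr <- function(series, brain_mask) {
  d <- dim(series$values)
  nt <- d[4]
  if (nt < 20L) warning("SFNR over fewer than 20 frames is unstable")
  idx <- which(brain_mask)
  if (!length(idx)) stop("empty mask")
  mat <- matrix(series$values, prod(d[1:3]), nt)[idx, , drop = FALSE]
  mu <- rowMeans(mat)
  res <- poly2_residuals(mat)
  s <- sqrt(rowSums(res^2) / max(nt - 3L, 1L))
  sfnr <- ifelse(s > 0, mu / s, NA_real_)
  map <- array(NA_real_, d[1:3])
  map[idx] <- sfnr
  n_zero <- sum(s == 0)
  med <- if (all(s == 0)) NA_real_
         else stats::median(sfnr[s > 0])
  list(sfnr_map = map, median_sfnr = med, n_zero_sd = n_zero)
}

#' Per-frame outlier voxel fraction
#'
#' Each voxel's trend is its temporal median; a time point is an outlier
#' when its absolute deviation from the trend exceeds
#' `qnorm(1 - alpha/2) * sqrt(pi/2) * mean(|deviation|)` — with the mean
#' absolute deviation, `sqrt(pi/2) * meanAD` is a consistent Gaussian sigma
#' estimate, so the rule is calibrated to flag a fraction of about `alpha`
#' on Gaussian noise. The per-frame fraction is taken over mask voxels with
#' a non-zero deviation scale.
#'
#' @param series a [qc_series].
#' @param brain_mask logical array.
#' @param alpha two-sided tail probability (default 0.001).
#' @return list with `fraction` (per frame), `threshold_k` (the sigma
#'   multiplier used), `n_zero_mad`.
#' @export
outlier_fraction <- function(series, brain_mask, alpha = 0.001) {
  d <- dim(series$values)
  nt <- d[4]
  if (nt < 20L) warning("outlier fractions over fewer than 20 frames are unstable")
  idx <- which(brain_mask)
  if (!length(idx)) stop("empty mask")
  mat <- matrix(series$values, prod(d[1:3]), nt)[idx, , drop = FALSE]
  med <- apply(mat, 1L, stats::median)
  dev <- abs(mat - med)
  mad_v <- rowMeans(dev)
  k <- stats::qnorm(1 - alpha / 2) * sqrt(pi / 2)
  keep <- mad_v > 0
  n_zero <- sum(!keep)
  if (!any(keep))
    return(list(fraction = rep(0, nt), threshold_k = k,
                n_zero_mad = n_zero))
  thr <- k * mad_v[keep]
  fraction <- colMeans(dev[keep, , drop = FALSE] > thr)
  list(fraction = fraction, threshold_k = k, n_zero_mad = n_zero)
}

#' Volume-mean running difference ("velocity")
#'
#' @param series a [qc_series].
#' @return per-frame vector; element t is the mean over all voxels of
#'   frame t minus frame t-1, with 0 at the first frame.
#' @export
velocity <- function(series) {
  d <- dim(series$values)
  m <- colMeans(matrix(series$values, prod(d[1:3]), d[4]))
  c(0, diff(m))
}

#' Frequency-spectrum summary of the mean in-mask signal
#'
#' The within-mask mean time series is demeaned and Fourier transformed;
#' the magnitude spectrum over the positive-frequency bins (DC excluded) is
#' summarised by its mean and maximum. Frequencies are in Hz when the
#' series carries a TR, otherwise cycles/frame (with a warning).
#'
#' @param series a [qc_series].
#' @param brain_mask logical array.
#' @return list with `spectrum` (data.frame frequency/magnitude),
#'   `spectrum_mean`, `spectrum_max`, `peak_frequency`, `frequency_unit`.
#' @export
spectrum_stats <- function(series, brain_mask) {
  d <- dim(series$values)
  idx <- which(brain_mask)
  if (!length(idx)) stop("empty mask")
  nt <- d[4]
  ts <- colMeans(matrix(series$values, prod(d[1:3]), nt)[idx, ,
                                                         drop = FALSE])
  tr <- series$frame_interval
  unit <- "Hz"
  if (is.null(tr)) {
    warning("no TR in series; spectrum frequencies are in cycles/frame")
    tr <- 1
    unit <- "cycles/frame"
  }
  mag <- Mod(stats::fft(ts - mean(ts)))
  nb <- nt %/% 2L
  bins <- seq_len(nb)                       # DC excluded
  freq <- bins / (nt * tr)
  mag <- mag[bins + 1L]
  list(spectrum = data.frame(frequency = freq, magnitude = mag),
       spectrum_mean = mean(mag), spectrum_max = max(mag),
       peak_frequency = freq[which.max(mag)], frequency_unit = unit)
}

#' Frame-wise structural descriptors
#'
#' Reuses the structural operators frame by frame: volume mean intensity,
#' head centre-of-mass offset (per-frame 10% head partition) and its change
#' from the first frame, per-axis FWHM, and the per-slice intensity
#' variation (SD over time of each slice's mean intensity).
#'
#' @param series a [qc_series].
#' @param brain_mask logical array used for FWHM estimation.
#' @param fwhm compute per-frame FWHM (default TRUE; the costliest part).
#' @return list with `volume_mean`, `com_offset` (frames x 3),
#'   `com_change` (frames x 3, relative to frame 1), `fwhm` (frames x 3 or
#'   NULL), `slice_variation` (per slice).
#' @export
per_frame_descriptors <- function(series, brain_mask, fwhm = TRUE) {
  d <- dim(series$values)
  nt <- d[4]
  volume_mean <- numeric(nt)
  com_offset <- matrix(NA_real_, nt, 3,
                       dimnames = list(NULL, c("x", "y", "z")))
  fwhm_mat <- if (fwhm)
    matrix(NA_real_, nt, 3, dimnames = list(NULL, c("x", "y", "z")))
  msi_mat <- matrix(NA_real_, nt, d[series$slice_axis])
  for (t in seq_len(nt)) {
    fr <- get_frame(series, t)
    volume_mean[t] <- mean(fr$values)
    msi_mat[t, ] <- mean_slice_intensity(fr)
    part <- tryCatch(partition_head_background(fr), error = function(e) NULL)
    if (!is.null(part))
      com_offset[t, ] <- center_of_mass(fr, part$head_mask)$offset_mm
    if (fwhm) {
      est <- tryCatch(
        estimate_fwhm(fr, brain_mask, min_voxels = min(1000L, sum(brain_mask))),
        error = function(e) NULL)
      if (!is.null(est)) fwhm_mat[t, ] <- est$fwhm
    }
  }
  com_change <- sweep(com_offset, 2L, com_offset[1, ], `-`)
  slice_variation <- apply(msi_mat, 2L, sd_pop)
  list(volume_mean = volume_mean, com_offset = com_offset,
       com_change = com_change, fwhm = fwhm_mat,
       slice_variation = slice_variation)
}

#' Full fMRI QC report
#'
#' Pipeline: head/brain masking on the temporal mean volume, rigid motion
#' estimation, then every scalar and plotted metric. The scalar summary
#' block carries the six headline values: maximum FD, the FD > 0.5 count,
#' average temporal SNR, maximum and minimum DVARS, and the DVARS > 50
#' count.
#'
#' @param series a [qc_series].
#' @param fd_threshold FD exceedance threshold in mm (default 0.5).
#' @param dvars_threshold DVARS exceedance threshold (default 50).
#' @param head_radius FD rotation radius in mm (default 50).
#' @param motion estimate rigid motion (default TRUE; the slowest step).
#' @param per_frame compute frame-wise descriptors (default TRUE).
#' @param external_brain_mask optional logical array.
#' @return object of class `qc_functional_metrics`.
#' @export
functional_report <- function(series, fd_threshold = 0.5,
                              dvars_threshold = 50, head_radius = 50,
                              motion = TRUE, per_frame = TRUE,
                              external_brain_mask = NULL) {
  d <- dim(series$values)
  mean_vol <- qc_volume(array(rowMeans(matrix(series$values,
                                              prod(d[1:3]), d[4])),
                              d[1:3]),
                        voxel_size = series$voxel_size,
                        slice_axis = series$slice_axis)
  partition <- partition_head_background(mean_vol)
  partition <- extract_brain_mask(mean_vol, partition, external_brain_mask)
  mask <- partition$brain_mask

  rigid <- NULL; fd <- NULL
  if (motion) {
    # register on the dilated bright-object mask: it includes the
    # high-contrast object edge but not the noise-only background that the
    # lower-decile head/background split leaves inside its "head" region
    rigid <- estimate_motion(series, dilate3d(partition$brain_mask))
    fd <- framewise_displacement(rigid, head_radius = head_radius,
                                 threshold = fd_threshold)
  }
  dvars <- compute_dvars(series, mask, threshold = dvars_threshold)
  tsnr <- temporal_snr(series, mask)
  sfnr <- if (d[4] >= 20L) compute_sfnr(series, mask) else NULL
  outliers <- if (d[4] >= 20L) outlier_fraction(series, mask) else NULL
  vel <- velocity(series)
  spec <- if (!is.null(series$frame_interval))
    spectrum_stats(series, mask) else NULL
  frames <- if (per_frame) per_frame_descriptors(series, mask) else NULL

  scalars <- c(
    max_fd = if (!is.null(fd)) fd$max_fd else NA_real_,
    n_fd_above = if (!is.null(fd)) fd$n_above else NA_real_,
    avg_tsnr = tsnr$avg_tsnr,
    max_dvars = dvars$max_dvars,
    min_dvars = dvars$min_dvars,
    n_dvars_above = dvars$n_above)
  structure(list(
    scalars = scalars,
    fd = fd, dvars = dvars, tsnr = tsnr, sfnr = sfnr,
    outliers = outliers, velocity = vel, spectrum = spec,
    per_frame = frames, rigid = rigid, partition = partition,
    thresholds = c(fd = fd_threshold, dvars = dvars_threshold),
    directionality = c(max_fd = "higher_is_worse",
                       n_fd_above = "higher_is_worse",
                       avg_tsnr = "lower_is_worse",
                       max_dvars = "higher_is_worse",
                       min_dvars = "higher_is_worse",
                       n_dvars_above = "higher_is_worse")),
    class = "qc_functional_metrics")
}

#' @export
print.qc_functional_metrics <- function(x, ...) {
  cat("<qc_functional_metrics>\n")
  for (nm in names(x$scalars))
    cat(sprintf("  %-14s %s\n", nm,
                ifelse(is.na(x$scalars[nm]), "--",
                       signif(x$scalars[nm], 5))))
  invisible(x)
}
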