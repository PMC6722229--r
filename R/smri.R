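#' Structural MRI / CT quality metrics
#'
#' Eight no-reference quantities summarise a 3D scan: the per-slice mean
#' intensity vector (MSI), four noise ratios (SNR, SVNR, CNR, CVNR), the
#' tissue contrast-to-tissue variation index (TCTV), per-axis image
#' smoothness as FWHM estimated from the variance of first derivatives, and
#' the brain centre of mass. A phantom profile adds the odd-even slice
#' intensity difference.
#'
#' @name smri_metrics
NULL

#' Mean slice intensity vector
#'
#' @param vol a [qc_volume].
#' @param slice_axis slice dimension; defaults to the volume's own.
#' @return numeric vector, element k = mean intensity of slice k.
#' @export
mean_slice_intensity <- function(vol, slice_axis = vol$slice_axis) {
  apply(vol$values, slice_axis, mean)
}

#' Signal-to-noise ratio
#'
#' Mean head intensity over background SD. Lower SNR indicates poorer
#' image quality.
#'
#' @param stats a `qc_tissue_stats`.
#' @return scalar; `NA` (flagged undefined) when the background SD is zero.
#' @export
compute_snr <- function(stats) {
  if (!is.finite(stats$sd_background) || stats$sd_background == 0)
    return(NA_real_)
  stats$mu_head / stats$sd_background
}

#' Signal variance-to-noise variance ratio
#'
#' Head intensity variance over background intensity variance. Higher SVNR
#' indicates bad image quality.
#'
#' @inheritParams compute_snr
#' @export
compute_svnr <- function(stats) {
  if (!is.finite(stats$var_background) || stats$var_background == 0)
    return(NA_real_)
  stats$var_head / stats$var_background
}

#' Contrast-to-noise ratio
#'
#' Absolute GM-WM mean intensity difference over background SD. Lower CNR
#' indicates poorer image quality.
#'
#' @inheritParams compute_snr
#' @export
compute_cnr <- function(stats) {
  if (!is.finite(stats$mu_gm) || !is.finite(stats$mu_wm) ||
      !is.finite(stats$sd_background) || stats$sd_background == 0)
    return(NA_real_)
  abs(stats$mu_gm - stats$mu_wm) / stats$sd_background
}

#' Contrast of variance-to-noise ratio
#'
#' As CNR but with the GM/WM intensity SDs in place of the means:
#' `|sd_GM - sd_WM| / sd_background`.
#'
#' @inheritParams compute_snr
#' @export
compute_cvnr <- function(stats) {
  if (!is.finite(stats$sd_gm) || !is.finite(stats$sd_wm) ||
      !is.finite(stats$sd_background) || stats$sd_background == 0)
    return(NA_real_)
  abs(stats$sd_gm - stats$sd_wm) / stats$sd_background
}

#' Tissue contrast-to-tissue variation
#'
#' Absolute GM-WM mean difference over the quadrature-pooled GM/WM SD,
#' `sqrt(sd_GM^2 + sd_WM^2)`. Smaller TCTV indicates poorer image quality;
#' the index is particularly sensitive to motion.
#'
#' @inheritParams compute_snr
#' @export
compute_tctv <- function(stats) {
  if (!is.finite(stats$mu_gm) || !is.finite(stats$mu_wm) ||
      !is.finite(stats$sd_gm) || !is.finite(stats$sd_wm))
    return(NA_real_)
  pooled <- sqrt(stats$sd_gm^2 + stats$sd_wm^2)
  num <- abs(stats$mu_gm - stats$mu_wm)
  if (pooled == 0) {
    if (num == 0) return(NA_real_)   # 0/0 undefined
    return(Inf)
  }
  num / pooled
}

# variance of within-mask first forward differences along axis `a`
diff_var_axis <- function(v, mask, a) {
  d <- dim(v)
  idx_lo <- slice.index(v, a) < d[a]
  pair <- mask & idx_lo
  # shift mask/values by one along axis a
  shift_back <- function(x) {
    perm <- c(a, setdiff(1:3, a))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xs <- xp[c(2:dp[1], 1), , , drop = FALSE]
    aperm(xs, order(perm))
  }
  mask_next <- shift_back(mask)
  ok <- pair & mask_next
  if (sum(ok) < 2L) return(NA_real_)
  dif <- shift_back(v) - v
  var_pop(dif[ok])
}

#' Image smoothness as per-axis FWHM (variance-of-derivatives method)
#'
#' For each axis the ratio of the first-difference variance to twice the
#' image variance inside the mask gives the lag-1 autocorrelation
#' `r = 1 - var(diff)/(2 var)`; under a Gaussian autocorrelation model the
#' smoothness is `FWHM = voxel * sqrt(-2 log 2 / log r)`. Estimates below
#' the voxel size (white noise limit, r <= 1/4) are clamped to the voxel
#' size and flagged. Also returns the number of resolvable elements: brain
#' voxel count divided by the geometric mean of the per-axis FWHM (the
#' literal definition used here; set `resel_convention = "product"` for the
#' conventional resel count).
#'
#' @param vol a [qc_volume].
#' @param mask logical array (brain mask); needs `min_voxels` voxels.
#' @param min_voxels floor on mask size (default 1000).
#' @param resel_convention `"geometric_mean"` (default) or `"product"`.
#' @return list with `fwhm` (per-axis mm, names x/y/z), `magnitude`,
#'   `resolvable_elements`, `r` (per-axis autocorrelation) and per-axis
#'   `flags` (`"ok"`, `"floor"`, `"unresolved"`).
#' @export
estimate_fwhm <- function(vol, mask, min_voxels = 1000L,
                          resel_convention = c("geometric_mean", "product")) {
  resel_convention <- match.arg(resel_convention)
  n <- sum(mask)
  if (n < min_voxels)
    stop("FWHM estimation needs >= ", min_voxels, " mask voxels, got ", n)
  v <- vol$values
  v_mask <- v[mask]
  v0 <- var_pop(v_mask)
  if (!is.finite(v0) || v0 == 0)
    stop("FWHM undefined: zero intensity variance inside the mask")
  fwhm <- rep(NA_real_, 3)
  r <- rep(NA_real_, 3)
  flags <- rep("unresolved", 3)
  for (a in 1:3) {
    dv <- diff_var_axis(v, mask, a)
    if (!is.finite(dv)) next
    r[a] <- 1 - dv / (2 * v0)
    if (r[a] >= 1) next                       # flat along this axis
    raw <- if (r[a] > 0)
      vol$voxel_size[a] * sqrt(-2 * log(2) / log(r[a])) else 0
    if (raw < vol$voxel_size[a]) {
      fwhm[a] <- vol$voxel_size[a]            # white-noise floor
      flags[a] <- "floor"
    } else {
      fwhm[a] <- raw
      flags[a] <- "ok"
    }
  }
  names(fwhm) <- names(r) <- names(flags) <- c("x", "y", "z")
  magnitude <- if (all(is.finite(fwhm))) sqrt(sum(fwhm^2)) else NA_real_
  resel <- if (all(is.finite(fwhm))) {
    if (resel_convention == "geometric_mean")
      n / exp(mean(log(fwhm)))
    else
      n / prod(fwhm / vol$voxel_size)
  } else NA_real_
  list(fwhm = fwhm, magnitude = magnitude, resolvable_elements = resel,
       r = r, flags = flags)
}

#' Centre of mass of a mask
#'
#' Unweighted centroid of the mask voxel indices (0-based), converted to mm,
#' plus the offset from the grid centre and its Euclidean magnitude. The
#' offset form is acquisition-size invariant and is what auto-QC consumes.
#'
#' @param vol a [qc_volume] (geometry source).
#' @param mask logical array, non-empty.
#' @return list with `centroid_mm`, `offset_mm`, `magnitude`.
#' @export
center_of_mass <- function(vol, mask) {
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  d <- dim(vol$values)
  coords <- arrayInd(idx, d) - 1L               # 0-based voxel indices
  centroid <- colMeans(coords) * vol$voxel_size
  grid_center <- (d - 1) / 2 * vol$voxel_size
  offset <- centroid - grid_center
  names(centroid) <- names(offset) <- c("x", "y", "z")
  list(centroid_mm = centroid, offset_mm = offset,
       magnitude = sqrt(sum(offset^2)))
}

#' Odd-even slice intensity difference
#'
#' Mean MSI over odd-indexed slices minus mean MSI over even-indexed slices
#' (0-based slice indexing); a phantom stability index for interleaved
#' acquisitions.
#'
#' @inheritParams mean_slice_intensity
#' @export
odd_even_slice_difference <- function(vol, slice_axis = vol$slice_axis) {
  msi <- mean_slice_intensity(vol, slice_axis)
  k <- seq_along(msi) - 1L                      # 0-based
  mean(msi[k %% 2L == 1L]) - mean(msi[k %% 2L == 0L])
}

#' Full structural QC report
#'
#' Runs the whole structural pipeline: head/background partition, brain
#' extraction, tissue segmentation (skipped for `ct` and `phantom`
#' profiles), and all metrics. Unavailable metrics carry explicit flags.
#'
#' @param vol a [qc_volume].
#' @param profile acquisition profile: `"t1"` (default), `"t2"`, `"flair"`,
#'   `"ct"`, `"phantom"`. T2/FLAIR invert the tissue contrast ordering;
#'   CT and phantom profiles skip tissue segmentation and phantom adds the
#'   odd-even slice difference.
#' @param background_fraction passed to [partition_head_background()].
#' @param external_brain_mask optional logical array bypassing brain
#'   extraction.
#' @param seed segmentation restart seed.
#' @param fwhm_min_voxels passed to [estimate_fwhm()].
#' @return object of class `qc_structural_metrics`: named scalars, vectors,
#'   per-metric availability flags and directionality metadata.
#' @export
structural_report <- function(vol, profile = c("t1", "t2", "flair", "ct",
                                               "phantom"),
                              background_fraction = 0.10,
                              external_brain_mask = NULL, seed = 42L,
                              fwhm_min_voxels = 1000L) {
  profile <- match.arg(profile)
  segment <- !(profile %in% c("ct", "phantom"))
  ordering <- if (profile == "t1") c("csf", "gm", "wm")
              else c("wm", "gm", "csf")         # T2/FLAIR: CSF bright
  partition <- partition_head_background(vol, background_fraction)
  partition <- extract_brain_mask(vol, partition, external_brain_mask)
  labels <- NULL
  if (segment)
    labels <- segment_tissues(vol, partition$brain_mask, ordering, seed)
  st <- tissue_stats(vol, partition, labels)

  msi <- mean_slice_intensity(vol)
  scalars <- c(snr = compute_snr(st), svnr = compute_svnr(st),
               cnr = if (segment) compute_cnr(st) else NA_real_,
               cvnr = if (segment) compute_cvnr(st) else NA_real_,
               tctv = if (segment) compute_tctv(st) else NA_real_)
  fwhm <- tryCatch(
    estimate_fwhm(vol, partition$brain_mask, min_voxels = fwhm_min_voxels),
    error = function(e) NULL)
  com <- center_of_mass(vol, partition$brain_mask)
  flags <- c(
    msi = "ok",
    snr = if (is.finite(scalars["snr"])) "ok" else "undefined",
    svnr = if (is.finite(scalars["svnr"])) "ok" else "undefined",
    cnr = if (!segment) "unavailable"
          else if (is.finite(scalars["cnr"])) "ok" else "undefined",
    cvnr = if (!segment) "unavailable"
           else if (is.finite(scalars["cvnr"])) "ok" else "undefined",
    tctv = if (!segment) "unavailable"
           else if (is.finite(scalars["tctv"])) "ok" else "undefined",
    fwhm = if (is.null(fwhm)) "undefined"
           else if (all(fwhm$flags == "ok")) "ok" else "flagged",
    com = "ok")
  directionality <- c(snr = "lower_is_worse", svnr = "higher_is_worse",
                      cnr = "lower_is_worse", cvnr = "higher_is_worse",
                      tctv = "lower_is_worse", fwhm = "higher_is_worse",
                      com = "higher_is_worse")
  structure(list(
    profile = profile,
    msi = msi,
    scalars = scalars,
    fwhm = fwhm,
    com = com,
    odd_even_difference = if (profile == "phantom")
      odd_even_slice_difference(vol) else NULL,
    stats = st,
    tissue_degenerate = if (segment) labels$degenerate else NA,
    partition = partition,
    flags = flags,
    directionality = directionality), class = "qc_structural_metrics")
}

#' @export
print.qc_structural_metrics <- function(x, ...) {
  cat("<qc_structural_metrics> profile:", x$profile, "\n")
  sc <- x$scalars
  for (nm in names(sc))
    cat(sprintf("  %-5s %10s  [%s]\n", nm,
                ifelse(is.na(sc[nm]), "--", signif(sc[nm], 5)),
                x$flags[nm]))
  if (!is.null(x$fwhm))
    cat(sprintf("  fwhm  %s mm (magnitude %.3f)\n",
                paste(signif(x$fwhm$fwhm, 4), collapse = "/"),
                x$fwhm$magnitude))
  cat(sprintf("  com   offset magnitude %.3f mm\n", x$com$magnitude))
  invisible(x)
}
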