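#' Diffusion MRI quality metrics and tensor fitting
#'
#' Per-gradient-direction descriptors (MSI, SNR, centre-of-mass
#' displacement about the series mean), within-head-mask intensity
#' histograms, a per-slice descriptive report, and log-linear
#' least-squares diffusion tensor fits yielding FA, MD and ADC maps.
#'
#' @name dti_metrics
NULL

#' Per-gradient MSI, SNR and centre-of-mass displacement
#'
#' MSI and SNR reuse the structural definitions on each gradient volume:
#' the SNR background region comes from the supplied (b0-derived)
#' partition. The CoM of each gradient volume is computed from a per-frame
#' head partition (the 10% intensity rule applied to that frame) so that a
#' displaced frame actually moves its CoM; displacements are reported about
#' the per-axis mean over frames and therefore sum to zero.
#'
#' @param series a [qc_series] of gradient volumes.
#' @param scheme a [qc_gradients] (validated against the frame count).
#' @param partition a `qc_partition` derived from the b0 frame.
#' @return list with `msi` (per-frame volume mean), `snr`,
#'   `com_displacement` (frames x 3 mm, mean-centred per axis).
#' @export
per_gradient_metrics <- function(series, scheme, partition) {
  nt <- n_frames(series)
  if (length(scheme$b_values) != nt)
    stop("gradient scheme has ", length(scheme$b_values),
         " entries but the series has ", nt, " frames")
  sd_bg <- sd_pop(NULL)
  msi <- numeric(nt); snr <- numeric(nt)
  com <- matrix(NA_real_, nt, 3, dimnames = list(NULL, c("x", "y", "z")))
  bg_idx <- which(partition$background_mask)
  head_idx <- which(partition$head_mask)
  for (t in seq_len(nt)) {
    fr <- get_frame(series, t)
    msi[t] <- mean(fr$values)
    sd_bg <- sd_pop(fr$values[bg_idx])
    snr[t] <- if (is.finite(sd_bg) && sd_bg > 0)
      mean(fr$values[head_idx]) / sd_bg else NA_real_
    part_t <- tryCatch(partition_head_background(fr),
                       error = function(e) NULL)
    if (!is.null(part_t))
      com[t, ] <- center_of_mass(fr, part_t$head_mask)$centroid_mm
  }
  com_disp <- sweep(com, 2L, colMeans(com, na.rm = TRUE), `-`)
  list(msi = msi, snr = snr, com_displacement = com_disp)
}

#' Within-mask intensity histograms per gradient volume
#'
#' @param series a [qc_series].
#' @param scheme a [qc_gradients].
#' @param head_mask logical array (b0-derived head mask), non-empty.
#' @param n_bins histogram bin count per volume (default 100).
#' @return list of per-frame lists: `breaks`, `counts`, and descriptive
#'   `stats` (mean, sd, min, max, median, q1, q3; SD is population SD).
#' @export
gradient_histograms <- function(series, scheme, head_mask, n_bins = 100L) {
  idx <- which(head_mask)
  if (!length(idx)) stop("empty head mask")
  nt <- n_frames(series)
  lapply(seq_len(nt), function(t) {
    x <- get_frame(series, t)$values[idx]
    r <- range(x)
    if (r[1] == r[2]) {
      breaks <- c(r[1] - 0.5, r[1] + 0.5)
      counts <- length(x)
    } else {
      breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
      counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                         n_bins)
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    list(breaks = breaks, counts = counts,
         stats = c(mean = mean(x), sd = sd_pop(x), min = r[1], max = r[2],
                   median = q[2], q1 = q[1], q3 = q[3]))
  })
}

# analytic eigenvalues of a symmetric 3x3 matrix given its 6 unique
# elements (xx, yy, zz, xy, xz, yz); falls back to eigen() near-degenerate
sym3_eigenvalues <- function(m) {
  eigen(matrix(m[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3), symmetric = TRUE,
        only.values = TRUE)$values
}

#' Fit diffusion tensors and derive FA/MD/ADC maps
#'
#' Per-voxel unweighted log-linear least squares on
#' `log(S_g / S_0) = -b g' D g`, with `S_0` the mean of the b=0 frames.
#' Eigenvalues of the fitted tensor give MD (mean eigenvalue) and FA; the
#' ADC map is the direction-averaged apparent coefficient
#' `mean_g( -log(S_g/S_0) / b_g )`. Voxels with a non-positive signal in
#' any frame are flagged and excluded. FA is reported for the fitted
#' eigenvalues as `sqrt(3/2) * ||lambda - MD|| / ||lambda||`; fits with
#' negative eigenvalues are flagged in `negative_eigenvalue_mask`, not
#' silently clipped.
#'
#' @param series a [qc_series] of gradient volumes.
#' @param scheme a [qc_gradients]; needs at least 6 non-collinear
#'   diffusion-weighted directions plus a b=0 frame.
#' @param brain_mask logical array of voxels to fit.
#' @param max_condition largest acceptable condition number of the design
#'   matrix (default 1e6); collinear direction sets error out.
#' @return list with `fa_map`, `md_map`, `adc_map`, `b0_map` (3D arrays,
#'   NA outside the fitted voxels), `nonpositive_signal_mask`,
#'   `negative_eigenvalue_mask`.
#' @export
fit_tensor <- function(series, scheme, brain_mask, max_condition = 1e6) {
  d <- dim(series$values)
  nt <- d[4]
  if (length(scheme$b_values) != nt)
    stop("gradient scheme does not match the series frame count")
  b0 <- scheme$b_values <= scheme$b0_tolerance
  dwi <- which(!b0)
  if (length(dwi) < 6L)
    stop("tensor fitting needs >= 6 diffusion-weighted directions")
  g <- scheme$directions[, dwi, drop = FALSE]
  b <- scheme$b_values[dwi]
  # design: columns Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
  X <- cbind(b * g[1, ]^2, b * g[2, ]^2, b * g[3, ]^2,
             2 * b * g[1, ] * g[2, ], 2 * b * g[1, ] * g[3, ],
             2 * b * g[2, ] * g[3, ])
  sv <- svd(X)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > max_condition)
    stop("rank-deficient gradient design (condition number ",
         format(cond, digits = 4), "); directions are collinear")
  idx <- which(brain_mask)
  if (!length(idx)) stop("empty brain mask")
  nv <- prod(d[1:3])
  mat <- matrix(series$values, nv, nt)[idx, , drop = FALSE]
  s0 <- rowMeans(mat[, b0, drop = FALSE])
  sg <- mat[, dwi, drop = FALSE]
  pos <- s0 > 0 & apply(sg > 0, 1L, all)
  fit_idx <- idx[pos]
  fa <- md <- adc <- rep(NA_real_, length(fit_idx))
  neg_eig <- logical(length(fit_idx))
  if (length(fit_idx)) {
    Y <- -log(sg[pos, , drop = FALSE] / s0[pos])     # voxels x ndwi
    coefs <- t(qr.solve(X, t(Y)))                    # voxels x 6
    adc <- rowMeans(sweep(Y, 2L, b, `/`))
    for (i in seq_len(nrow(coefs))) {
      lam <- sym3_eigenvalues(coefs[i, ])
      mdi <- mean(lam)
      md[i] <- mdi
      nrm <- sqrt(sum(lam^2))
      fa[i] <- if (nrm > 0) sqrt(1.5) * sqrt(sum((lam - mdi)^2)) / nrm
               else 0
      neg_eig[i] <- any(lam < 0)
    }
  }
  mk_map <- function(vals, at) {
    m <- array(NA_real_, d[1:3]); m[at] <- vals; m
  }
  b0_map <- array(rowMeans(matrix(series$values, nv, nt)[, b0,
                                                         drop = FALSE]),
                  d[1:3])
  npos <- array(FALSE, d[1:3]); npos[idx[!pos]] <- TRUE
  nege <- array(FALSE, d[1:3]); nege[fit_idx[neg_eig]] <- TRUE
  list(fa_map = mk_map(fa, fit_idx), md_map = mk_map(md, fit_idx),
       adc_map = mk_map(adc, fit_idx), b0_map = b0_map,
       nonpositive_signal_mask = npos, negative_eigenvalue_mask = nege,
       condition_number = cond)
}

#' Per-slice descriptive report
#'
#' One row per (gradient volume, slice): voxel count, mean, SD (population),
#' minimum and maximum intensity. With a mask, statistics cover the mask
#' voxels in that slice; empty slices get `n_voxels = 0` and NA statistics.
#'
#' @param series a [qc_series].
#' @param scheme a [qc_gradients].
#' @param mask optional logical array restricting the statistics.
#' @return data.frame with columns gradient, slice, n_voxels, mean, sd,
#'   min, max.
#' @export
slice_report <- function(series, scheme, mask = NULL) {
  d <- dim(series$values)
  nt <- n_frames(series)
  if (length(scheme$b_values) != nt)
    stop("gradient scheme does not match the series frame count")
  ax <- series$slice_axis
  ns <- d[ax]
  rows <- vector("list", nt * ns)
  k <- 0L
  for (t in seq_len(nt)) {
    fr <- get_frame(series, t)$values
    for (s in seq_len(ns)) {
      sl <- switch(ax, fr[s, , ], fr[, s, ], fr[, , s])
      if (!is.null(mask)) {
        msl <- switch(ax, mask[s, , ], mask[, s, ], mask[, , s])
        sl <- sl[msl]
      }
      k <- k + 1L
      rows[[k]] <- if (length(sl))
        data.frame(gradient = t, slice = s, n_voxels = length(sl),
                   mean = mean(sl), sd = sd_pop(sl),
                   min = min(sl), max = max(sl))
      else
        data.frame(gradient = t, slice = s, n_voxels = 0L,
                   mean = NA_real_, sd = NA_real_,
                   min = NA_real_, max = NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Full DTI QC report
#'
#' Validates the gradient scheme against the series, derives the head
#' partition from the b0 frame, and computes the per-gradient vectors,
#' histograms, slice report and tensor maps.
#'
#' @param series a [qc_series].
#' @param scheme a [qc_gradients].
#' @param fit fit the diffusion tensor (default TRUE).
#' @return object of class `qc_diffusion_metrics`.
#' @export
diffusion_report <- function(series, scheme, fit = TRUE) {
  nt <- n_frames(series)
  if (length(scheme$b_values) != nt)
    stop("gradient scheme has ", length(scheme$b_values),
         " entries but the series has ", nt, " frames")
  b0_idx <- which(scheme$b_values <= scheme$b0_tolerance)[1]
  b0_frame <- get_frame(series, b0_idx)
  partition <- partition_head_background(b0_frame)
  partition <- extract_brain_mask(b0_frame, partition)
  per_grad <- per_gradient_metrics(series, scheme, partition)
  hists <- gradient_histograms(series, scheme, partition$head_mask)
  slices <- slice_report(series, scheme, mask = partition$head_mask)
  tensor <- if (fit)
    tryCatch(fit_tensor(series, scheme, partition$brain_mask),
             error = function(e) {
               warning("tensor fit failed: ", conditionMessage(e))
               NULL
             }) else NULL
  structure(list(per_gradient = per_grad, histograms = hists,
                 slice_report = slices, tensor = tensor,
                 partition = partition, b0_index = b0_idx),
            class = "qc_diffusion_metrics")
}

#' @export
print.qc_diffusion_metrics <- function(x, ...) {
  cat("<qc_diffusion_metrics> ", length(x$per_gradient$msi),
      " gradient volumes\n", sep = "")
  if (!is.null(x$tensor))
    cat(sprintf("  FA median %.3f, MD median %.3e\n",
                stats::median(x$tensor$fa_map, na.rm = TRUE),
                stats::median(x$tensor$md_map, na.rm = TRUE)))
  invisible(x)
}
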