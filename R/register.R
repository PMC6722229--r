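# Rigid-body registration by normalized-correlation maximisation.
#
# Parameterisation: p = (tx, ty, tz, rx, ry, rz) — translations in mm,
# rotations in radians about the x/y/z axes applied as R = Rz %*% Ry %*% Rx
# around the volume centre. The transform maps reference-space coordinates
# into the moving frame: sampling the moving frame at T(x) and comparing
# with the reference at x. Recovered parameters therefore equal the motion
# that was applied to the object.

rotation_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# trilinear interpolation of `v` at continuous 0-based voxel indices
trilinear <- function(v, xi, yi, zi, fill = 0) {
  d <- dim(v)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  inb <- xi >= 0 & xi <= d[1] - 1L & yi >= 0 & yi <= d[2] - 1L &
         zi >= 0 & zi <= d[3] - 1L
  out <- rep(fill, length(xi))
  if (!any(inb)) return(out)
  x0 <- pmin(x0[inb], d[1] - 2L); fx <- xi[inb] - x0
  y0 <- pmin(y0[inb], d[2] - 2L); fy <- yi[inb] - y0
  z0 <- pmin(z0[inb], d[3] - 2L); fz <- zi[inb] - z0
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  base <- 1L + x0 * sx + y0 * sy + z0 * sz
  vv <- as.vector(v)
  c000 <- vv[base];           c100 <- vv[base + sx]
  c010 <- vv[base + sy];      c110 <- vv[base + sx + sy]
  c001 <- vv[base + sz];      c101 <- vv[base + sx + sz]
  c011 <- vv[base + sy + sz]; c111 <- vv[base + sx + sy + sz]
  w <- c000 * (1 - fx) * (1 - fy) * (1 - fz) +
       c100 * fx * (1 - fy) * (1 - fz) +
       c010 * (1 - fx) * fy * (1 - fz) +
       c110 * fx * fy * (1 - fz) +
       c001 * (1 - fx) * (1 - fy) * fz +
       c101 * fx * (1 - fy) * fz +
       c011 * (1 - fx) * fy * fz +
       c111 * fx * fy * fz
  out[inb] <- w
  out
}

# mm coordinates (n x 3) of 0-based voxel indices
grid_coords_mm <- function(d, voxel_size, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(prod(d))
  coords <- arrayInd(idx, d) - 1L
  sweep(coords, 2L, voxel_size, `*`)
}

# sample `values` at T(x) (forward) or T^-1(x) (invert = TRUE) for the given
# reference-space mm coordinates; returns a vector aligned with coords rows
sample_rigid <- function(values, voxel_size, coords_mm, params, center_mm,
                         invert = FALSE, fill = 0) {
  R <- rotation_matrix(params[4], params[5], params[6])
  t <- params[1:3]
  if (invert) {
    xy <- sweep(coords_mm, 2L, center_mm + t, `-`) %*% R  # R^-1 = t(R), x %*% R = t(R) %*% x
    xy <- sweep(xy, 2L, center_mm, `+`)
  } else {
    xy <- sweep(coords_mm, 2L, center_mm, `-`) %*% t(R)
    xy <- sweep(xy, 2L, center_mm + t, `+`)
  }
  trilinear(values,
            xy[, 1] / voxel_size[1],
            xy[, 2] / voxel_size[2],
            xy[, 3] / voxel_size[3], fill = fill)
}

# apply a rigid motion to a volume (object moves by `params`)
apply_rigid <- function(values, voxel_size, params, fill = 0) {
  d <- dim(values)
  coords <- grid_coords_mm(d, voxel_size)
  center <- (d - 1) / 2 * voxel_size
  out <- sample_rigid(values, voxel_size, coords, params, center,
                      invert = TRUE, fill = fill)
  array(out, d)
}

# 2x block-mean downsample (trailing odd voxels dropped)
downsample2 <- function(v) {
  d <- dim(v)
  d2 <- d %/% 2L
  if (any(d2 < 4L)) return(NULL)
  v <- v[seq_len(2L * d2[1]), seq_len(2L * d2[2]), seq_len(2L * d2[3]),
         drop = FALSE]
  v <- v[seq(1, 2 * d2[1], 2), , , drop = FALSE] +
       v[seq(2, 2 * d2[1], 2), , , drop = FALSE]
  v <- v[, seq(1, 2 * d2[2], 2), , drop = FALSE] +
       v[, seq(2, 2 * d2[2], 2), , drop = FALSE]
  v <- v[, , seq(1, 2 * d2[3], 2), drop = FALSE] +
       v[, , seq(2, 2 * d2[3], 2), drop = FALSE]
  v / 8
}

neg_ncorr <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  -stats::cor(a, b)
}

register_level <- function(ref, mov, voxel_size, mask_idx, init,
                           maxit = 400L, polish = FALSE) {
  d <- dim(ref)
  coords <- grid_coords_mm(d, voxel_size, mask_idx)
  center <- (d - 1) / 2 * voxel_size
  ref_v <- ref[mask_idx]
  cost <- function(p) {
    s <- sample_rigid(mov, voxel_size, coords, p, center)
    neg_ncorr(ref_v, s)
  }
  fit <- stats::optim(init, cost, method = "Nelder-Mead",
                      control = list(parscale = c(1, 1, 1,
                                                  0.02, 0.02, 0.02),
                                     maxit = maxit, reltol = 1e-12))
  if (polish) {
    # restart with a tighter simplex (Nelder-Mead can stall early), then a
    # quasi-Newton polish with small finite-difference steps
    fit <- stats::optim(fit$par, cost, method = "Nelder-Mead",
                        control = list(parscale = c(0.1, 0.1, 0.1,
                                                    0.002, 0.002, 0.002),
                                       maxit = maxit, reltol = 1e-12))
    bf <- tryCatch(
      stats::optim(fit$par, cost, method = "BFGS",
                   control = list(ndeps = rep(1e-4, 6), reltol = 1e-14,
                                  maxit = 200L)),
      error = function(e) NULL)
    if (!is.null(bf) && bf$value <= fit$value) fit <- bf
  }
  fit
}

# intensity-weighted centre of mass in mm (for translation initialisation)
intensity_com <- function(v, voxel_size) {
  d <- dim(v)
  w <- v - min(v)
  s <- sum(w)
  if (s == 0) return((d - 1) / 2 * voxel_size)
  cx <- vapply(1:3, function(a)
    sum(apply(w, a, sum) * (seq_len(d[a]) - 1)) / s, numeric(1))
  cx * voxel_size
}

#' Estimate rigid head motion across a 4D series
#'
#' Each frame is aligned to the first frame by maximising the normalized
#' correlation over the mask, with a two-level multiresolution
#' Nelder-Mead search initialised at the intensity centre-of-mass offset.
#' The rotation centre is the volume centre; interpolation is trilinear.
#'
#' @param series a [qc_series].
#' @param brain_mask logical array in the reference frame's grid; the cost
#'   is evaluated on a once-dilated copy so object edges are included.
#' @param presmooth_fwhm Gaussian pre-smoothing of both images before the
#'   cost, in voxel units (default 2). Without it, trilinear interpolation
#'   of a noisy moving frame smooths its noise and biases the optimum
#'   toward spurious off-grid rotations; smoothing both images removes
#'   that asymmetry. Set to 0 to disable.
#' @return object of class `qc_rigid_params`: `params` is an
#'   `n_frames x 6` matrix (tx, ty, tz in mm; rx, ry, rz in radians), first
#'   row zero; `converged` per frame.
#' @export
estimate_motion <- function(series, brain_mask, presmooth_fwhm = 2) {
  nt <- n_frames(series)
  d <- dim(series$values)[1:3]
  if (!identical(dim(brain_mask), d)) stop("mask grid mismatch")
  if (!any(brain_mask)) stop("empty mask")
  mask <- dilate3d(brain_mask)
  vs <- series$voxel_size
  smooth_fr <- function(v) {
    if (presmooth_fwhm <= 0) return(v)
    gaussian_smooth3d(v, vs, presmooth_fwhm * vs)
  }
  ref <- smooth_fr(array(series$values[, , , 1], d))
  # coarse pyramid level
  ref2 <- downsample2(ref)
  use_pyramid <- !is.null(ref2)
  if (use_pyramid) mask2_idx <- which(downsample2(mask + 0) > 0)
  mask_idx <- which(mask)
  params <- matrix(0, nt, 6,
                   dimnames = list(NULL, c("tx", "ty", "tz",
                                           "rx", "ry", "rz")))
  converged <- rep(TRUE, nt)
  com_ref <- intensity_com(ref, vs)
  for (t in 2:nt) {
    mov <- smooth_fr(array(series$values[, , , t], d))
    init <- c(intensity_com(mov, vs) - com_ref, 0, 0, 0)
    p <- init
    ok <- TRUE
    if (use_pyramid) {
      fit2 <- tryCatch(
        register_level(ref2, downsample2(mov), vs * 2, mask2_idx, p,
                       maxit = 300L),
        error = function(e) NULL)
      if (!is.null(fit2)) p <- fit2$par else ok <- FALSE
    }
    fit <- tryCatch(register_level(ref, mov, vs, mask_idx, p, maxit = 400L,
                                   polish = TRUE),
                    error = function(e) NULL)
    if (is.null(fit)) {
      params[t, ] <- NA_real_
      converged[t] <- FALSE
    } else {
      params[t, ] <- fit$par
      converged[t] <- ok && fit$convergence == 0
    }
  }
  structure(list(params = params, converged = converged),
            class = "qc_rigid_params")
}
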