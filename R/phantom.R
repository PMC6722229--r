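#' Synthetic phantoms with retrievable ground truth
#'
#' Head-shaped phantoms are nested ellipsoids — scalp/skull, CSF, GM, WM —
#' with piecewise-constant class intensities, optional bias field,
#' ghosting, blur and Rician or Gaussian noise. 4D functional series add
#' rigid motion events, polynomial drift and spike artifacts; diffusion
#' series are generated from per-compartment tensors via the
#' mono-exponential signal model. Every generator is fully determined by
#' the spec's seed and returns its ground truth alongside the image.
#'
#' @name synthetic_phantoms
NULL

#' Phantom specification
#'
#' Defaults describe a 64 mm^3-scale T1-like head phantom at 1 mm isotropic
#' resolution: class means 30/70/110 for CSF/GM/WM, scalp 45, Rician noise
#' sigma 5 (a realistic SNR regime for modern 3T structural imaging), no
#' artifacts. 4D defaults: 3 mm voxels on a 32 x 32 x 20 grid, TR 3 s,
#' 50 frames. Diffusion defaults: WM tensor diag(1.7, 0.2, 0.2) x 1e-3
#' mm^2/s, GM 0.8e-3 isotropic, CSF 3.0e-3 isotropic.
#'
#' @param shape grid size per axis (voxels).
#' @param voxel_size mm per axis.
#' @param geometry `"head"` (nested ellipsoids) or `"uniform"` (single
#'   ellipsoid of constant intensity, a BIRN-style QA phantom).
#' @param center_offset_mm head centre offset from the grid centre.
#' @param semiaxes named list of mm semi-axes for `head`, `csf`, `gm`,
#'   `wm` (nested); scaled defaults are derived from `shape` when `NULL`.
#' @param intensities named class means (`head`, `csf`, `gm`, `wm`;
#'   `uniform` for the uniform geometry).
#' @param noise_sigma noise magnitude (image units).
#' @param noise_type `"rician"` (MR magnitude, default) or `"gaussian"`.
#' @param bias_amplitude peak fractional amplitude of a quadratic
#'   multiplicative bias field (0 = off).
#' @param ghost_fraction intensity fraction of an N/2 ghost replica
#'   (0 = off); `ghost_axis` is the phase-encode axis.
#' @param ghost_axis axis of the ghost shift.
#' @param smoothing_fwhm mm of Gaussian blur applied to the noise-free
#'   image (0 = off).
#' @param texture_amplitude fractional amplitude of the deterministic
#'   anatomy-like intensity texture inside the brain (4D renders only;
#'   default 0.12). The texture is defined in object coordinates, so it
#'   moves rigidly with the head.
#' @param n_frames,frame_interval 4D series length and TR (seconds).
#' @param motion_events list of `list(frame =, translation = mm-3vector,
#'   rotation = deg-3vector)`; the head stays at the new position.
#' @param drift_coefs polynomial coefficients (linear, quadratic, ...) of
#'   a multiplicative drift in normalised time t in [0, 1].
#' @param spike_events list of `list(frame =, fraction =, amplitude =)`;
#'   `amplitude` is in units of the noise sigma.
#' @param tensors named list of 3x3 diffusion tensors (mm^2/s) per
#'   compartment; defaults as above.
#' @param s0_scale multiplier turning structural intensities into b0
#'   signal.
#' @param seed integer; fully determines the generated data.
#' @return object of class `qc_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size = c(1, 1, 1),
                         geometry = c("head", "uniform"),
                         center_offset_mm = c(0, 0, 0), semiaxes = NULL,
                         intensities = c(head = 45, csf = 30, gm = 70,
                                         wm = 110, uniform = 400),
                         noise_sigma = 5,
                         noise_type = c("rician", "gaussian"),
                         bias_amplitude = 0, ghost_fraction = 0,
                         ghost_axis = 2L, smoothing_fwhm = 0,
                         texture_amplitude = 0.12,
                         n_frames = 50L, frame_interval = 3,
                         motion_events = list(), drift_coefs = numeric(0),
                         spike_events = list(), tensors = NULL,
                         s0_scale = 4, seed = 1L) {
  geometry <- match.arg(geometry)
  noise_type <- match.arg(noise_type)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  extent <- shape * voxel_size
  if (is.null(semiaxes)) {
    # anisotropic (head-like) so rigid rotations are observable
    head <- extent / 2 * c(0.70, 0.84, 0.80)
    semiaxes <- list(head = head, csf = head * 0.83,
                     gm = head * 0.71, wm = head * 0.44)
  }
  if (is.null(tensors)) {
    tensors <- list(head = diag(3) * 1.0e-3,
                    csf = diag(3) * 3.0e-3,
                    gm = diag(3) * 0.8e-3,
                    wm = diag(c(1.7e-3, 0.2e-3, 0.2e-3)))
  }
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 geometry = geometry, center_offset_mm = center_offset_mm,
                 semiaxes = semiaxes, intensities = intensities,
                 noise_sigma = noise_sigma, noise_type = noise_type,
                 bias_amplitude = bias_amplitude,
                 ghost_fraction = ghost_fraction,
                 ghost_axis = as.integer(ghost_axis),
                 smoothing_fwhm = smoothing_fwhm,
                 texture_amplitude = texture_amplitude,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 motion_events = motion_events,
                 drift_coefs = drift_coefs, spike_events = spike_events,
                 tensors = tensors, s0_scale = s0_scale,
                 seed = as.integer(seed)),
            class = "qc_phantom_spec")
}

# squared normalised ellipsoid coordinate for every voxel
ellipsoid_r2 <- function(shape, voxel_size, center_mm, semiaxes_mm) {
  ax <- lapply(1:3, function(a)
    ((axis_mm(shape[a], voxel_size[a]) - center_mm[a]) / semiaxes_mm[a])^2)
  outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
}

# compartment label array: 0 bg, 1 scalp/skull, 2 csf, 3 gm, 4 wm.
# `rigid` (tx,ty,tz mm, rx,ry,rz rad about the grid centre) moves the
# object analytically — the geometry is evaluated at inverse-transformed
# coordinates, so moved phantoms carry no interpolation error.
# inner compartments are deliberately off-centre (fractions of the head
# semi-axes) so the phantom, like a real head, has no rotational symmetry
COMPARTMENT_OFFSET_FRAC <- list(head = c(0, 0, 0), csf = c(0, 0, 0),
                                gm = c(0.02, -0.05, 0.03),
                                wm = c(0.06, -0.10, 0.08))

phantom_labels <- function(spec, rigid = NULL) {
  d <- spec$shape
  center <- (d - 1) / 2 * spec$voxel_size + spec$center_offset_mm
  comps <- if (spec$geometry == "uniform") "head"
           else c("head", "csf", "gm", "wm")
  lab <- array(0L, d)
  if (is.null(rigid) || all(rigid == 0)) {
    for (i in seq_along(comps)) {
      ci <- center + COMPARTMENT_OFFSET_FRAC[[comps[i]]] *
        spec$semiaxes$head
      r2 <- ellipsoid_r2(d, spec$voxel_size, ci,
                         spec$semiaxes[[comps[i]]])
      lab[r2 <= 1] <- i
    }
    return(lab)
  }
  grid_c <- (d - 1) / 2 * spec$voxel_size
  R <- rotation_matrix(rigid[4], rigid[5], rigid[6])
  x <- grid_coords_mm(d, spec$voxel_size)
  x <- sweep(x, 2L, grid_c + rigid[1:3], `-`) %*% R    # = R^-1 (y - c - t)
  x <- sweep(x, 2L, grid_c, `+`)
  for (i in seq_along(comps)) {
    ax <- spec$semiaxes[[comps[i]]]
    ci <- center + COMPARTMENT_OFFSET_FRAC[[comps[i]]] *
      spec$semiaxes$head
    r2 <- ((x[, 1] - ci[1]) / ax[1])^2 +
          ((x[, 2] - ci[2]) / ax[2])^2 +
          ((x[, 3] - ci[3]) / ax[3])^2
    lab[r2 <= 1] <- i
  }
  lab
}

# Analytic soft-edge (partial-volume) render of the phantom intensity
# field under an optional rigid motion. Compartment membership is
# pnorm(signed_distance / edge_mm); with edge_mm about one voxel the
# rendered edges are band-limited, so rigidly moved frames carry no
# quantisation error and registration can be validated at sub-voxel
# accuracy. edge_mm = 0 reproduces the hard piecewise-constant render.
phantom_field <- function(spec, rigid = NULL, edge_mm = 0) {
  if (edge_mm <= 0)
    return(phantom_intensity(spec, phantom_labels(spec, rigid)))
  d <- spec$shape
  center <- (d - 1) / 2 * spec$voxel_size + spec$center_offset_mm
  grid_c <- (d - 1) / 2 * spec$voxel_size
  x <- grid_coords_mm(d, spec$voxel_size)
  if (!is.null(rigid) && any(rigid != 0)) {
    R <- rotation_matrix(rigid[4], rigid[5], rigid[6])
    x <- sweep(x, 2L, grid_c + rigid[1:3], `-`) %*% R
    x <- sweep(x, 2L, grid_c, `+`)
  }
  comps <- if (spec$geometry == "uniform") "head"
           else c("head", "csf", "gm", "wm")
  ints <- if (spec$geometry == "uniform")
    c(spec$intensities[["uniform"]])
  else spec$intensities[c("head", "csf", "gm", "wm")]
  v <- numeric(nrow(x))
  prev <- 0
  w_brain <- NULL
  for (i in seq_along(comps)) {
    ax <- spec$semiaxes[[comps[i]]]
    ci <- center + COMPARTMENT_OFFSET_FRAC[[comps[i]]] *
      spec$semiaxes$head
    r <- sqrt(((x[, 1] - ci[1]) / ax[1])^2 +
              ((x[, 2] - ci[2]) / ax[2])^2 +
              ((x[, 3] - ci[3]) / ax[3])^2)
    scale <- exp(mean(log(ax)))              # ~mm per unit of r
    w <- stats::pnorm((1 - r) * scale / edge_mm)
    w[w < 1e-6] <- 0                         # keep the background exactly 0
    w[w > 1 - 1e-9] <- 1
    v <- v + (ints[[i]] - prev) * w
    prev <- ints[[i]]
    if (comps[i] == "gm") w_brain <- w
  }
  # anatomy-like intensity texture riding in object coordinates: it moves
  # rigidly with the head and gives registration something to grip besides
  # the outer edge (a featureless blob leaves in-plane rotation nearly
  # unobservable)
  if (spec$texture_amplitude > 0 && !is.null(w_brain)) {
    xo <- sweep(x, 2L, center, `-`)
    tex <- sin(2 * pi * (0.9 * xo[, 1] + 0.45 * xo[, 2]) / 17) *
           sin(2 * pi * (xo[, 2] - 0.6 * xo[, 3]) / 23) +
           sin(2 * pi * (0.5 * xo[, 1] + xo[, 3]) / 13)
    v <- v + spec$texture_amplitude * spec$intensities[["gm"]] *
      tex * w_brain
  }
  array(v, d)
}

phantom_intensity <- function(spec, lab) {
  v <- array(0, dim(lab))
  if (spec$geometry == "uniform") {
    v[lab == 1L] <- spec$intensities[["uniform"]]
  } else {
    for (i in 1:4)
      v[lab == i] <- spec$intensities[[c("head", "csf", "gm", "wm")[i]]]
  }
  v
}

# separable circular Gaussian smoothing via FFT
gaussian_smooth3d <- function(v, voxel_size, fwhm_mm) {
  if (all(fwhm_mm <= 0)) return(v)
  fwhm_mm <- rep_len(fwhm_mm, 3)
  d <- dim(v)
  kf <- lapply(1:3, function(a) {
    if (fwhm_mm[a] <= 0) return(rep(1, d[a]))
    sigma <- fwhm_mm[a] / (2 * sqrt(2 * log(2))) / voxel_size[a]
    x <- seq_len(d[a]) - 1
    x <- pmin(x, d[a] - x)                      # circular distance
    k <- exp(-x^2 / (2 * sigma^2))
    Re(stats::fft(k / sum(k)))
  })
  K <- outer(outer(kf[[1]], kf[[2]]), kf[[3]])
  Re(stats::fft(stats::fft(v) * K, inverse = TRUE)) / prod(d)
}

apply_common_artifacts <- function(v, spec) {
  d <- dim(v)
  if (spec$smoothing_fwhm > 0)
    v <- gaussian_smooth3d(v, spec$voxel_size, spec$smoothing_fwhm)
  if (spec$bias_amplitude != 0) {
    u <- lapply(1:3, function(a) seq(-1, 1, length.out = d[a]))
    r2 <- outer(outer(u[[1]]^2, u[[2]]^2, `+`), u[[3]]^2, `+`) / 3
    v <- v * (1 + spec$bias_amplitude * (r2 - 0.5))
  }
  if (spec$ghost_fraction > 0) {
    shift <- d[spec$ghost_axis] %/% 2L
    idx <- ((seq_len(d[spec$ghost_axis]) - 1L + shift) %%
              d[spec$ghost_axis]) + 1L
    ghost <- switch(spec$ghost_axis,
                    v[idx, , , drop = FALSE],
                    v[, idx, , drop = FALSE],
                    v[, , idx, drop = FALSE])
    v <- v + spec$ghost_fraction * ghost
  }
  v
}

add_noise <- function(v, sigma, type) {
  if (sigma <= 0) return(v)
  d <- dim(v)
  n <- prod(d)
  if (type == "gaussian") {
    v + array(stats::rnorm(n, 0, sigma), d)
  } else {
    sqrt((v + array(stats::rnorm(n, 0, sigma), d))^2 +
           array(stats::rnorm(n, 0, sigma), d)^2)
  }
}

#' Generate a structural phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [qc_volume]), and ground truth: `labels`
#'   (a `qc_tissue_labels`-compatible coding inside the brain), `head_mask`,
#'   `brain_mask`, `compartments` (raw 0-4 label array), `class_means`.
#' @export
make_structural <- function(spec) {
  lab <- phantom_labels(spec)
  clean <- apply_common_artifacts(phantom_intensity(spec, lab), spec)
  noisy <- with_seed(spec$seed,
                     add_noise(clean, spec$noise_sigma, spec$noise_type))
  vol <- qc_volume(noisy, voxel_size = spec$voxel_size)
  tissue <- array(0L, dim(lab))
  tissue[lab == 2L] <- 1L      # CSF
  tissue[lab == 3L] <- 2L      # GM
  tissue[lab == 4L] <- 3L      # WM
  list(volume = vol,
       compartments = lab,
       head_mask = lab > 0L,
       brain_mask = lab >= 2L,
       labels = structure(list(labels = tissue, degenerate = FALSE,
                               ordering = c("csf", "gm", "wm")),
                          class = "qc_tissue_labels"),
       class_means = spec$intensities,
       clean = clean)
}

# cumulative rigid position per frame from impulse motion events
motion_schedule <- function(n_frames, events) {
  params <- matrix(0, n_frames, 6,
                   dimnames = list(NULL, c("tx", "ty", "tz",
                                           "rx", "ry", "rz")))
  if (!length(events)) return(params)
  delta <- matrix(0, n_frames, 6)
  for (ev in events) {
    f <- ev$frame
    if (f < 2 || f > n_frames) stop("motion event frame out of range")
    tr <- rep_len(ev$translation %||% c(0, 0, 0), 3)
    ro <- rep_len(ev$rotation %||% c(0, 0, 0), 3) * pi / 180
    delta[f, ] <- delta[f, ] + c(tr, ro)
  }
  apply(delta, 2L, cumsum)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a functional (4D) phantom series
#'
#' Frames are the rigidly displaced noise-free base phantom, multiplied by
#' the polynomial drift, plus noise; spike events add `amplitude * sigma`
#' to a random fraction of head voxels in one frame. Motion events are
#' persistent: the head moves at the event frame and stays. The true rigid
#' parameters per frame are returned.
#'
#' @param spec a [phantom_spec()].
#' @return list with `series` (a [qc_series]), `motion_params`
#'   (n_frames x 6 truth matrix, mm / radians), `event_frames`,
#'   `brain_mask`, `head_mask`, `base` (noise-free reference volume).
#' @export
make_functional <- function(spec) {
  base <- make_structural(phantom_spec_quiet(spec))
  d <- spec$shape
  nt <- spec$n_frames
  params <- motion_schedule(nt, spec$motion_events)
  # noise-free clean frame per distinct head position, rendered
  # analytically with soft (one-voxel) edges so moved frames carry no
  # quantisation error
  qspec <- phantom_spec_quiet(spec)
  edge <- max(spec$voxel_size)
  pos_cache <- new.env(parent = emptyenv())
  clean_at <- function(p) {
    key <- paste(signif(p, 12), collapse = ",")
    got <- pos_cache[[key]]
    if (!is.null(got)) return(got)
    fr <- apply_common_artifacts(phantom_field(qspec, p, edge), qspec)
    pos_cache[[key]] <- fr
    fr
  }
  drift <- rep(1, nt)
  if (length(spec$drift_coefs)) {
    tn <- seq(0, 1, length.out = nt)
    for (k in seq_along(spec$drift_coefs))
      drift <- drift + spec$drift_coefs[k] * tn^k
  }
  sig <- spec$noise_sigma
  arr <- array(0, c(d, nt))
  with_seed(spec$seed, {
    for (t in seq_len(nt)) {
      fr <- clean_at(params[t, ])
      fr <- fr * drift[t]
      fr <- add_noise(fr, sig, spec$noise_type)
      arr[, , , t] <- fr
    }
    for (ev in spec$spike_events) {
      f <- ev$frame
      head_idx <- which(base$head_mask)
      pick <- sample(head_idx, max(1L, round(ev$fraction *
                                               length(head_idx))))
      amp <- ev$amplitude * max(sig, 1)
      fr <- arr[, , , f]
      fr[pick] <- fr[pick] + amp
      arr[, , , f] <- fr
    }
  })
  series <- qc_series(arr, voxel_size = spec$voxel_size,
                      frame_interval = spec$frame_interval)
  list(series = series, motion_params = params,
       event_frames = vapply(spec$motion_events, `[[`, numeric(1),
                             "frame"),
       brain_mask = base$brain_mask, head_mask = base$head_mask,
       base = base$volume)
}

# copy of the spec with noise disabled (the 4D generator adds its own)
phantom_spec_quiet <- function(spec) {
  q <- spec
  q$noise_sigma <- 0
  q
}

#' Generate a diffusion-weighted phantom series
#'
#' Per compartment, `S_g = S0 * exp(-b g' D g)` with `S0` the structural
#' class intensity times `s0_scale`; optional Rician/Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [qc_gradients].
#' @return list with `series`, `tensors` (per compartment), `compartments`
#'   (label array), `brain_mask`, `head_mask`, `s0` (noise-free b0 volume).
#' @export
make_diffusion <- function(spec, scheme) {
  lab <- phantom_labels(spec)
  s0 <- phantom_intensity(spec, lab) * spec$s0_scale
  d <- spec$shape
  nt <- length(scheme$b_values)
  comp_names <- c("head", "csf", "gm", "wm")
  arr <- array(0, c(d, nt))
  for (t in seq_len(nt)) {
    b <- scheme$b_values[t]
    g <- scheme$directions[, t]
    fr <- array(0, d)
    for (i in 1:4) {
      sel <- lab == i
      if (!any(sel)) next
      D <- spec$tensors[[comp_names[i]]]
      att <- exp(-b * as.numeric(t(g) %*% D %*% g))
      fr[sel] <- s0[sel] * att
    }
    arr[, , , t] <- fr
  }
  if (spec$noise_sigma > 0)
    arr <- with_seed(spec$seed,
                     add_noise(arr, spec$noise_sigma, spec$noise_type))
  list(series = qc_series(arr, voxel_size = spec$voxel_size),
       tensors = spec$tensors, compartments = lab,
       brain_mask = lab >= 2L, head_mask = lab > 0L,
       s0 = s0)
}

#' Simulate a reference population of structural scans
#'
#' Samples `n` head phantoms with mild between-scan variation (noise sigma
#' uniform on 3-6, 10% intensity jitter, ~2 mm centre jitter). A fraction
#' `prevalence` of scans (deterministic count `round(n * prevalence)`,
#' randomly placed) receive heavy artifacts — tripled noise, 4 mm blur and
#' a 15% ghost — and are labelled bad. Returns the structural metric table
#' and the truth labels, the substrate for cutoff calibration.
#'
#' @param n number of scans.
#' @param prevalence fraction of artifact-laden scans.
#' @param shape grid size (default 48^3 to keep runtime modest).
#' @param seed population seed.
#' @return list with `metrics` (data.frame: snr, svnr, cnr, cvnr, tctv,
#'   fwhm, com), `labels` (character good/bad), `specs`.
#' @export
make_reference_population <- function(n, prevalence = 0.2,
                                      shape = c(48, 48, 48), seed = 1L) {
  n_bad <- round(n * prevalence)
  cfg <- with_seed(seed, {
    bad <- rep(FALSE, n)
    if (n_bad > 0) bad[sample.int(n, n_bad)] <- TRUE
    lapply(seq_len(n), function(i) {
      list(bad = bad[i],
           sigma = stats::runif(1, 3, 6),
           gain = stats::runif(1, 0.9, 1.1),
           offset = stats::rnorm(3, 0, 2),
           seed = sample.int(1e6, 1))
    })
  })
  specs <- lapply(cfg, function(ci) {
    phantom_spec(
      shape = shape,
      intensities = c(head = 45, csf = 30, gm = 70, wm = 110,
                      uniform = 400) * ci$gain,
      center_offset_mm = ci$offset,
      noise_sigma = if (ci$bad) ci$sigma * 3 else ci$sigma,
      smoothing_fwhm = if (ci$bad) 4 else 0,
      ghost_fraction = if (ci$bad) 0.15 else 0,
      seed = ci$seed)
  })
  rows <- lapply(seq_len(n), function(i) {
    ph <- make_structural(specs[[i]])
    rep_i <- structural_report(ph$volume, profile = "t1",
                               fwhm_min_voxels = 500L)
    data.frame(snr = rep_i$scalars[["snr"]],
               svnr = rep_i$scalars[["svnr"]],
               cnr = rep_i$scalars[["cnr"]],
               cvnr = rep_i$scalars[["cvnr"]],
               tctv = rep_i$scalars[["tctv"]],
               fwhm = if (!is.null(rep_i$fwhm)) rep_i$fwhm$magnitude
                      else NA_real_,
               com = rep_i$com$magnitude)
  })
  list(metrics = do.call(rbind, rows),
       labels = ifelse(vapply(cfg, `[[`, logical(1), "bad"),
                       "bad", "good"),
       specs = specs)
}
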