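#' Head/background partition and tissue segmentation
#'
#' The SNR family of metrics needs three nested regions: the image
#' background (noise-only voxels), the head, and the brain, plus CSF/GM/WM
#' tissue classes inside the brain. The split is deliberately simple: the
#' lower tail of the intensity distribution is background; the brain is the
#' largest bright connected component inside the head; tissues are a 1-D
#' intensity clustering.
#'
#' @name head_partition
NULL

# ---- low-level binary morphology on padded grids ---------------------------

pad3d <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d + 2L)
  out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  out
}

unpad3d <- function(m) {
  d <- dim(m)
  m[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L)]
}

# linear-index offsets of the 26-neighbourhood (or 6-) in a padded grid
neigh_offsets <- function(d, conn = 26L) {
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  if (conn == 6L) {
    c(-sx, sx, -sy, sy, -sz, sz)
  } else {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
    g$dx * sx + g$dy * sy + g$dz * sz
  }
}

# flood fill inside padded logical `m` from linear seed indices
flood_fill <- function(m, seeds, offsets) {
  visited <- logical(length(m))
  visited[seeds] <- TRUE
  frontier <- seeds
  mv <- as.vector(m)
  while (length(frontier)) {
    cand <- unique(as.vector(outer(frontier, offsets, `+`)))
    cand <- cand[cand >= 1L & cand <= length(mv)]
    cand <- cand[mv[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

# largest 26-connected component of a logical 3D array
largest_component <- function(mask) {
  p <- pad3d(mask)
  offs <- neigh_offsets(dim(p), 26L)
  remaining <- as.vector(p)
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- flood_fill(array(remaining, dim(p)), seed, offs)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining[comp] <- FALSE
  }
  if (is.null(best)) return(mask & FALSE)
  unpad3d(array(best, dim(p)))
}

dilate3d <- function(mask, conn = 26L) {
  p <- pad3d(mask)
  offs <- neigh_offsets(dim(p), conn)
  out <- as.vector(p)
  idx <- which(p)
  for (o in offs) out[idx + o] <- TRUE
  unpad3d(array(out, dim(p)))
}

erode3d <- function(mask, conn = 26L) !dilate3d(!mask, conn)

close3d <- function(mask, conn = 26L) {
  # dilation runs on a doubly padded grid so border voxels are unaffected
  d <- dim(mask)
  big <- array(FALSE, d + 4L)
  big[3:(d[1] + 2L), 3:(d[2] + 2L), 3:(d[3] + 2L)] <- mask
  big <- erode3d(dilate3d(big, conn), conn)
  big[3:(d[1] + 2L), 3:(d[2] + 2L), 3:(d[3] + 2L)]
}

# fill cavities: anything not reachable from the border through the
# complement (6-connected) belongs to the object
fill_holes3d <- function(mask) {
  p <- pad3d(mask)
  comp <- !p
  d <- dim(p)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  seeds <- which(comp & border)
  outside <- flood_fill(comp, seeds, neigh_offsets(d, 6L))
  unpad3d(array(!outside, d) | p)
}

# Otsu threshold from a 256-bin histogram of `x`
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) stop("cannot threshold a constant region")
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  (breaks[k] + breaks[k + 1L]) / 2
}

# ---- public operations -----------------------------------------------------

#' Split a volume into background and head
#'
#' The lower `background_fraction` of the intensity distribution separates
#' the image background from the head: voxels at or below that sample
#' quantile are background, the rest are the head.
#'
#' @param vol a [qc_volume].
#' @param background_fraction proportion of the intensity distribution
#'   treated as background (default 0.10); must lie in (0, 0.5).
#' @return object of class `qc_partition` with logical arrays `head_mask`,
#'   `background_mask` (complementary) and a `brain_mask` slot (`NULL` until
#'   [extract_brain_mask()] fills it).
#' @export
partition_head_background <- function(vol, background_fraction = 0.10) {
  stopifnot(inherits(vol, "qc_volume"))
  if (background_fraction <= 0 || background_fraction >= 0.5)
    stop("`background_fraction` must be in (0, 0.5)")
  v <- vol$values
  if (min(v) == max(v))
    stop("degenerate input: constant image, background split impossible")
  q <- stats::quantile(as.vector(v), background_fraction, names = FALSE,
                       type = 7)
  background <- v <= q
  if (all(background) || !any(background))
    stop("degenerate input: background split produced an empty region")
  structure(list(head_mask = !background, background_mask = background,
                 brain_mask = NULL),
            class = "qc_partition")
}

#' Extract a brain mask from the head region
#'
#' The brain is taken as the largest 26-connected component of head voxels
#' above an Otsu threshold computed within the head, followed by one
#' morphological closing and a cavity fill. An externally supplied mask
#' bypasses segmentation entirely and is returned unchanged.
#'
#' @param vol a [qc_volume].
#' @param partition a `qc_partition` from [partition_head_background()].
#' @param external_mask optional logical array (same grid); when given it
#'   becomes the brain mask as-is.
#' @return the partition with `brain_mask` filled.
#' @export
extract_brain_mask <- function(vol, partition, external_mask = NULL) {
  stopifnot(inherits(partition, "qc_partition"))
  if (!is.null(external_mask)) {
    if (!identical(dim(external_mask), dim(vol$values)))
      stop("external mask grid does not match the volume")
    partition$brain_mask <- external_mask & TRUE
    return(partition)
  }
  head_idx <- which(partition$head_mask)
  if (!length(head_idx)) stop("empty head mask")
  thr <- otsu_threshold(vol$values[head_idx])
  bright <- partition$head_mask & (vol$values > thr)
  if (!any(bright))
    stop("brain segmentation failed (no voxels above threshold); ",
         "supply an external brain mask")
  brain <- fill_holes3d(close3d(largest_component(bright)))
  brain <- brain & partition$head_mask
  if (!any(brain))
    stop("brain segmentation failed (empty mask); supply an external mask")
  partition$brain_mask <- brain
  partition
}

#' Segment CSF/GM/WM by 1-D intensity clustering
#'
#' Three-class k-means (20 restarts, locally seeded) on the intensities
#' inside the brain mask. Classes are ordered by mean intensity and mapped
#' to tissues according to `ordering` — for T1-like contrast the darkest
#' class is CSF and the brightest WM.
#'
#' @param vol a [qc_volume].
#' @param brain_mask logical array.
#' @param ordering tissue names from darkest to brightest class; default
#'   `c("csf", "gm", "wm")` (T1-like). For T2-like contrast use
#'   `c("wm", "gm", "csf")`.
#' @param seed clustering restart seed (does not touch the caller's RNG).
#' @return object of class `qc_tissue_labels`: integer array `labels`
#'   (0 = outside brain, 1 = CSF, 2 = GM, 3 = WM), plus `degenerate` flag.
#' @export
segment_tissues <- function(vol, brain_mask, ordering = c("csf", "gm", "wm"),
                            seed = 42L) {
  stopifnot(setequal(ordering, c("csf", "gm", "wm")))
  idx <- which(brain_mask)
  if (!length(idx)) stop("empty brain mask")
  x <- vol$values[idx]
  labels <- array(0L, dim(vol$values))
  degenerate <- FALSE
  if (length(unique(x)) < 3L) {
    degenerate <- TRUE
  } else {
    km <- with_seed(seed, tryCatch(
      stats::kmeans(x, centers = 3L, nstart = 20L, iter.max = 100L),
      error = function(e) NULL))
    if (is.null(km) || length(unique(km$cluster)) < 3L) {
      degenerate <- TRUE
    } else {
      rank_by_mean <- rank(km$centers[, 1])       # 1 = darkest
      tissue_code <- c(csf = 1L, gm = 2L, wm = 3L)
      map <- tissue_code[ordering][rank_by_mean]  # cluster -> tissue code
      labels[idx] <- map[km$cluster]
    }
  }
  structure(list(labels = labels, degenerate = degenerate,
                 ordering = ordering),
            class = "qc_tissue_labels")
}

#' Region and tissue intensity statistics
#'
#' Means and SDs over the exact mask voxels; SDs use the population
#' convention (divisor N). Empty classes are flagged unavailable rather
#' than erroring.
#'
#' @param vol a [qc_volume].
#' @param partition a `qc_partition` (brain mask optional).
#' @param labels optional `qc_tissue_labels`; omit for CT/phantom profiles.
#' @return object of class `qc_tissue_stats`.
#' @export
tissue_stats <- function(vol, partition, labels = NULL) {
  v <- vol$values
  stopifnot(identical(dim(v), dim(partition$head_mask)))
  head_v <- v[partition$head_mask]
  bg_v <- v[partition$background_mask]
  out <- list(
    mu_head = mean(head_v), sd_head = sd_pop(head_v),
    var_head = var_pop(head_v),
    sd_background = sd_pop(bg_v), var_background = var_pop(bg_v),
    mu_gm = NA_real_, mu_wm = NA_real_, mu_csf = NA_real_,
    sd_gm = NA_real_, sd_wm = NA_real_, sd_csf = NA_real_,
    n_brain_voxels = if (is.null(partition$brain_mask)) NA_integer_
                     else sum(partition$brain_mask),
    tissues_available = FALSE)
  if (!is.null(labels) && !labels$degenerate) {
    for (cls in c("csf", "gm", "wm")) {
      code <- c(csf = 1L, gm = 2L, wm = 3L)[[cls]]
      xv <- v[labels$labels == code]
      if (length(xv)) {
        out[[paste0("mu_", cls)]] <- mean(xv)
        out[[paste0("sd_", cls)]] <- sd_pop(xv)
      }
    }
    out$tissues_available <- is.finite(out$mu_gm) && is.finite(out$mu_wm)
  }
  structure(out, class = "qc_tissue_stats")
}
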