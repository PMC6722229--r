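make_series <- function(arr, tr = 2) qc_series(arr, frame_interval = tr)

test_that("framewise displacement follows Power's construction", {
  p <- matrix(0, 6, 6)
  fd0 <- framewise_displacement(p)
  expect_equal(fd0$fd, rep(0, 6))
  expect_equal(fd0$n_above, 0)

  # single 0.6 mm x-translation jump between frames 4 and 5
  p[5:6, 1] <- 0.6
  fd <- framewise_displacement(p)
  expect_equal(fd$fd[5], 0.6)
  expect_equal(fd$fd[6], 0)
  expect_equal(fd$n_above, 1)
  expect_equal(fd$max_fd, 0.6)

  # 0.01 rad rotation step at 50 mm radius contributes 0.5 mm
  p2 <- matrix(0, 3, 6); p2[2:3, 4] <- 0.01
  fd2 <- framewise_displacement(p2)
  expect_equal(fd2$fd[2], 0.5)

  # invariance to a constant parameter offset
  p3 <- matrix(rnorm(36), 6, 6)
  off <- sweep(p3, 2, c(1, -2, 3, 0.1, 0.2, -0.1), `+`)
  expect_equal(framewise_displacement(p3)$fd,
               framewise_displacement(off)$fd, tolerance = 1e-12)

  # first-frame basis differs from frame-to-frame
  expect_equal(framewise_displacement(p, basis = "first_frame")$fd[6],
               0.6)
})

test_that("DVARS matches its RMS definition and normalization contract", {
  arr <- array(500, c(8, 8, 8, 5))
  mask <- array(TRUE, c(8, 8, 8))
  expect_equal(compute_dvars(make_series(arr), mask)$dvars, rep(0, 5))

  # one-voxel mask; mean volume median = 1000 so scaling is identity
  arr2 <- array(1000, c(8, 8, 8, 2)); arr2[1, 1, 1, ] <- c(970, 1030)
  m1 <- array(FALSE, c(8, 8, 8)); m1[1, 1, 1] <- TRUE
  dv <- compute_dvars(make_series(arr2), m1)
  expect_equal(dv$dvars, c(0, 60))
  expect_equal(dv$n_above, 1)

  # invariance under global intensity scaling
  set.seed(401)
  arr3 <- array(rnorm(8^3 * 6, 800, 30), c(8, 8, 8, 6))
  d1 <- compute_dvars(make_series(arr3), mask)$dvars
  d2 <- compute_dvars(make_series(arr3 * 3.21), mask)$dvars
  expect_lt(max(abs(d1 - d2) / pmax(d1, 1e-12)), 1e-9)
})

test_that("temporal SNR behaves like mean over SD", {
  set.seed(402)
  arr <- array(rnorm(8^3 * 200, 200, 10), c(8, 8, 8, 200))
  mask <- array(TRUE, c(8, 8, 8))
  ts <- temporal_snr(make_series(arr), mask)
  expect_equal(ts$avg_tsnr, 20, tolerance = 0.1)

  # halving sigma doubles tSNR
  set.seed(402)
  arr2 <- array(rnorm(8^3 * 200, 200, 5), c(8, 8, 8, 200))
  ts2 <- temporal_snr(make_series(arr2), mask)
  expect_equal(ts2$avg_tsnr / ts$avg_tsnr, 2, tolerance = 0.05)

  # constant series: all voxels zero-SD, average undefined
  tc <- temporal_snr(make_series(array(7, c(8, 8, 8, 12))), mask)
  expect_true(is.na(tc$avg_tsnr))
  expect_equal(tc$n_zero_sd, 512L)
})

test_that("SFNR removes polynomial drift and matches tSNR without it", {
  nt <- 200
  tn <- seq(0, 1, length.out = nt)
  mask <- array(TRUE, c(8, 8, 8))

  # pure quadratic drift, no noise: residual SD ~ 0 -> flagged
  arr <- array(0, c(8, 8, 8, nt))
  for (t in seq_len(nt))
    arr[, , , t] <- 100 * (1 + 0.2 * tn[t] + 0.1 * tn[t]^2)
  sf0 <- compute_sfnr(make_series(arr), mask)
  expect_equal(sf0$n_zero_sd + sum(sf0$sfnr_map > 1e6, na.rm = TRUE),
               512L)

  # drift + noise: SFNR ~ mean/sigma within 10%
  set.seed(403)
  arr2 <- arr * 2 + array(rnorm(8^3 * nt, 0, 10), c(8, 8, 8, nt))
  sf <- compute_sfnr(make_series(arr2), mask)
  expect_equal(sf$median_sfnr, mean(200 * (1 + 0.2 * tn + 0.1 * tn^2)) / 10,
               tolerance = 0.1)

  # equivalence with tSNR in the no-trend limit
  set.seed(404)
  arr3 <- array(rnorm(8^3 * nt, 300, 15), c(8, 8, 8, nt))
  s3 <- make_series(arr3)
  expect_equal(compute_sfnr(s3, mask)$median_sfnr,
               median(temporal_snr(s3, mask)$tsnr_map, na.rm = TRUE),
               tolerance = 0.02)
})

test_that("outlier fractions are alpha-calibrated and spike-sensitive", {
  set.seed(405)
  nt <- 120
  arr <- array(rnorm(10^3 * nt, 500, 12), c(10, 10, 10, nt))
  mask <- array(TRUE, c(10, 10, 10))
  of <- outlier_fraction(make_series(arr), mask)
  expect_gt(mean(of$fraction), 0.0005)
  expect_lt(mean(of$fraction), 0.002)

  # one frame with 5% of voxels displaced far beyond the threshold
  spiked <- arr
  idx <- sample.int(1000, 50)
  fr <- spiked[, , , 60]; fr[idx] <- fr[idx] + 200
  spiked[, , , 60] <- fr
  of2 <- outlier_fraction(make_series(spiked), mask)
  expect_equal(of2$fraction[60], 0.05 + mean(of$fraction),
               tolerance = 0.3)
  expect_gt(of2$fraction[60], 10 * median(of2$fraction))

  ofc <- outlier_fraction(make_series(array(3, c(8, 8, 8, 30))),
                          array(TRUE, c(8, 8, 8)))
  expect_equal(ofc$fraction, rep(0, 30))
})

test_that("velocity is the volume-mean running difference", {
  arr <- array(5, c(8, 8, 8, 6))
  expect_equal(velocity(make_series(arr)), rep(0, 6))

  arr[, , , 4] <- 10; arr[, , , 5] <- 10; arr[, , , 6] <- 10
  v <- velocity(make_series(arr))
  expect_equal(v[4], 5)
  expect_equal(v[5], 0)

  set.seed(406)
  arr2 <- array(rnorm(8^3 * 5), c(8, 8, 8, 5))
  m <- vapply(1:5, function(t) mean(arr2[, , , t]), numeric(1))
  expect_equal(velocity(make_series(arr2)), c(0, diff(m)),
               tolerance = 1e-12)
})

test_that("the frequency spectrum localises a pure oscillation", {
  nt <- 200
  sig <- 100 + 20 * sin(2 * pi * 0.1 * (0:(nt - 1)) * 2)   # 0.1 Hz at TR 2
  arr <- array(rep(sig, each = 8^3), c(8, 8, 8, nt))
  mask <- array(TRUE, c(8, 8, 8))
  sp <- spectrum_stats(make_series(arr, tr = 2), mask)
  expect_equal(sp$peak_frequency, 0.1)
  expect_equal(sp$frequency_unit, "Hz")

  sp0 <- spectrum_stats(make_series(array(9, c(8, 8, 8, 16)), tr = 2),
                        mask)
  expect_equal(sp0$spectrum_max, 0, tolerance = 1e-9)

  s_no_tr <- qc_series(arr, frame_interval = NULL)
  expect_warning(sp2 <- spectrum_stats(s_no_tr, mask), "cycles/frame")
  expect_equal(sp2$frequency_unit, "cycles/frame")
})

test_that("rigid motion is recovered on noise-free phantoms", {
  spec <- phantom_spec(shape = c(28, 28, 20), voxel_size = c(3, 3, 3),
                       noise_sigma = 0, n_frames = 4,
                       motion_events = list(
                         list(frame = 3,
                              translation = c(1.0, -0.5, 0.25)),
                         list(frame = 4, rotation = c(0, 0, 2))),
                       seed = 41)
  ph <- make_functional(spec)
  mot <- estimate_motion(ph$series, ph$head_mask)
  err <- mot$params - ph$motion_params
  expect_lt(max(abs(err[, 1:3])), 0.1)
  expect_lt(max(abs(err[, 4:6])) * 180 / pi, 0.2)
  expect_equal(unname(mot$params[1, ]), rep(0, 6))

  # identical frames: parameters are zero within optimizer tolerance
  static <- qc_series(array(rep(ph$series$values[, , , 1], 2),
                            c(28, 28, 20, 2)),
                      voxel_size = c(3, 3, 3))
  mot0 <- estimate_motion(static, ph$head_mask)
  expect_lt(max(abs(mot0$params[, 1:3])), 0.01)
  expect_lt(max(abs(mot0$params[, 4:6])) * 180 / pi, 0.01)
})

test_that("per-frame descriptors match direct structural calls", {
  spec <- phantom_spec(shape = c(24, 24, 16), voxel_size = c(3, 3, 3),
                       noise_sigma = 0, n_frames = 4,
                       motion_events = list(
                         list(frame = 3, translation = c(6, 0, 0))),
                       seed = 42)
  ph <- make_functional(spec)
  pf <- per_frame_descriptors(ph$series, ph$brain_mask, fwhm = FALSE)

  expect_equal(pf$com_change[1, ], c(x = 0, y = 0, z = 0))
  expect_gt(abs(pf$com_change[3, "x"]), 3)       # spike at the event frame
  expect_lt(abs(pf$com_change[2, "x"]), 0.5)

  fr2 <- get_frame(ph$series, 2)
  expect_equal(pf$volume_mean[2], mean(fr2$values))

  # static series: no CoM change, no slice variation
  static <- make_functional(phantom_spec(shape = c(24, 24, 16),
                                         voxel_size = c(3, 3, 3),
                                         noise_sigma = 0, n_frames = 3,
                                         seed = 43))
  pf0 <- per_frame_descriptors(static$series, static$brain_mask,
                               fwhm = FALSE)
  expect_equal(max(abs(pf0$com_change)), 0)
  expect_equal(max(pf0$slice_variation), 0)
})

test_that("functional report counts injected events and is deterministic", {
  spec <- phantom_spec(shape = c(24, 24, 16), voxel_size = c(3, 3, 3),
                       noise_sigma = 0, n_frames = 8,
                       motion_events = list(
                         list(frame = 3, translation = c(1.5, 0, 0)),
                         list(frame = 5, translation = c(0, -2, 0)),
                         list(frame = 7, rotation = c(0, 0, 2))),
                       seed = 44)
  ph <- make_functional(spec)
  rep <- functional_report(ph$series, per_frame = FALSE)
  expect_equal(unname(rep$scalars["n_fd_above"]), 3)
  expect_equal(names(rep$scalars),
               c("max_fd", "n_fd_above", "avg_tsnr", "max_dvars",
                 "min_dvars", "n_dvars_above"))

  clean <- make_functional(phantom_spec(shape = c(24, 24, 16),
                                        voxel_size = c(3, 3, 3),
                                        noise_sigma = 1, n_frames = 6,
                                        seed = 45))
  rc <- functional_report(clean$series, per_frame = FALSE)
  expect_equal(unname(rc$scalars["n_fd_above"]), 0)
  expect_equal(unname(rc$scalars["n_dvars_above"]), 0)

  rc2 <- functional_report(clean$series, per_frame = FALSE)
  expect_identical(rc$scalars, rc2$scalars)
  expect_identical(rc$dvars$dvars, rc2$dvars$dvars)
})
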