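test_that("mean slice intensity matches its definition", {
  vals <- array(0, c(8, 8, 10))
  for (k in 1:10) vals[, , k] <- k - 1
  vol <- qc_volume(vals)
  expect_equal(mean_slice_intensity(vol), 0:9)

  # in-slice permutation invariance
  set.seed(301)
  vals2 <- array(rnorm(8 * 8 * 10), c(8, 8, 10))
  volr <- qc_volume(vals2)
  perm <- vals2
  for (k in 1:10) perm[, , k] <- array(sample(vals2[, , k]), c(8, 8))
  expect_equal(mean_slice_intensity(qc_volume(perm)),
               mean_slice_intensity(volr), tolerance = 1e-12)

  # brute-force oracle on a noise volume
  set.seed(302)
  vals3 <- array(rnorm(32^3), c(32, 32, 32))
  msi <- mean_slice_intensity(qc_volume(vals3))
  oracle <- vapply(1:32, function(k) mean(vals3[, , k]), numeric(1))
  expect_equal(msi, oracle, tolerance = 1e-12)
})

test_that("noise-ratio formulas match hand arithmetic", {
  expect_equal(compute_snr(fake_stats(mu_head = 100, sd_background = 10)),
               10)
  expect_equal(compute_svnr(fake_stats(var_head = 400,
                                       var_background = 4)), 100)
  expect_equal(compute_svnr(fake_stats(var_head = 7, var_background = 7)),
               1)
  expect_equal(compute_cnr(fake_stats(mu_gm = 70, mu_wm = 110,
                                      sd_background = 8)), 5)
  expect_equal(compute_cnr(fake_stats(mu_gm = 80, mu_wm = 80,
                                      sd_background = 8)), 0)
  expect_equal(compute_cvnr(fake_stats(sd_gm = 12, sd_wm = 9,
                                       sd_background = 1.5)), 2)
  expect_equal(compute_cvnr(fake_stats(sd_gm = 9, sd_wm = 9,
                                       sd_background = 2)), 0)
  expect_equal(compute_tctv(fake_stats(mu_gm = 100, mu_wm = 150,
                                       sd_gm = 10, sd_wm = 10)),
               50 / sqrt(200))
  expect_equal(compute_tctv(fake_stats(mu_gm = 5, mu_wm = 5,
                                       sd_gm = 2, sd_wm = 1)), 0)
  expect_true(is.na(compute_tctv(fake_stats(mu_gm = 5, mu_wm = 5,
                                            sd_gm = 0, sd_wm = 0))))
})

test_that("ratio metrics agree with generative values on phantoms", {
  # constant head 100 over Gaussian background noise sigma 5: SNR = 20
  set.seed(303)
  d <- c(64, 64, 64)
  head <- scanqc:::ellipsoid_r2(d, c(1, 1, 1), c(31.5, 31.5, 31.5),
                                c(22, 26, 24)) <= 1
  vals <- array(rnorm(prod(d), 0, 5), d)
  vals[head] <- 100
  st <- tissue_stats(qc_volume(vals), truth_partition(head))
  expect_equal(compute_snr(st), 20, tolerance = 0.02)

  # generative variances 225 (head) and 25 (background): SVNR = 9
  set.seed(304)
  vals2 <- array(rnorm(prod(d), 0, 5), d)
  vals2[head] <- rnorm(sum(head), 500, 15)
  st2 <- tissue_stats(qc_volume(vals2), truth_partition(head))
  expect_equal(compute_svnr(st2), 9, tolerance = 9 * 0.05)

  # generative GM/WM means 70/110 over background sigma 8: CNR = 5
  ph <- make_structural(phantom_spec(noise_sigma = 8,
                                     noise_type = "gaussian", seed = 32))
  st3 <- tissue_stats(ph$volume,
                      truth_partition(ph$head_mask, ph$brain_mask),
                      ph$labels)
  expect_equal(compute_cnr(st3), 5, tolerance = 5 * 0.05)
})

test_that("added noise decreases TCTV in expectation", {
  tctvs <- vapply(1:8, function(s) {
    ph <- make_structural(small_spec(noise_sigma = 6,
                                     noise_type = "gaussian", seed = s))
    st <- tissue_stats(ph$volume,
                       truth_partition(ph$head_mask, ph$brain_mask),
                       ph$labels)
    compute_tctv(st)
  }, numeric(1))
  ph0 <- make_structural(small_spec(noise_sigma = 0))
  st0 <- tissue_stats(ph0$volume,
                      truth_partition(ph0$head_mask, ph0$brain_mask),
                      ph0$labels)
  # noise-free TCTV is infinite (zero within-class SD); any noise shrinks it
  expect_true(all(tctvs < 7))
  expect_equal(mean(tctvs), 40 / sqrt(2 * 36), tolerance = 0.1)
})

test_that("FWHM estimation recovers an applied kernel and floors noise", {
  set.seed(305)
  v <- array(rnorm(64^3), c(64, 64, 64))
  sm <- scanqc:::gaussian_smooth3d(v, c(1, 1, 1), 6)
  est <- estimate_fwhm(qc_volume(sm), array(TRUE, c(64, 64, 64)))
  expect_lt(max(abs(est$fwhm - 6)) / 6, 0.05)
  expect_equal(est$magnitude, sqrt(sum(est$fwhm^2)))
  expect_equal(est$resolvable_elements,
               64^3 / exp(mean(log(est$fwhm))))

  # unsmoothed white noise: r ~ 0, flagged at the voxel-size floor
  est0 <- estimate_fwhm(qc_volume(v), array(TRUE, c(64, 64, 64)))
  expect_true(all(est0$flags == "floor"))
  expect_equal(unname(est0$fwhm), c(1, 1, 1))
  expect_true(all(abs(est0$r) < 0.05))

  expect_error(estimate_fwhm(qc_volume(v),
                             array(FALSE, c(64, 64, 64))), ">= 1000")
})

test_that("centre of mass follows the mask centroid in mm", {
  vals <- array(1, c(16, 16, 16))
  vol <- qc_volume(vals, voxel_size = c(1, 1, 1))
  sym <- array(FALSE, c(16, 16, 16)); sym[6:11, 6:11, 6:11] <- TRUE
  cm <- center_of_mass(vol, sym)
  expect_equal(unname(cm$offset_mm), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(cm$magnitude, 0)

  single <- array(FALSE, c(16, 16, 16)); single[3, 4, 5] <- TRUE
  cm1 <- center_of_mass(vol, single)
  expect_equal(unname(cm1$centroid_mm), c(2, 3, 4))  # 0-based indices

  expect_error(center_of_mass(vol, array(FALSE, c(16, 16, 16))),
               "empty")
})

test_that("CoM is shift-equivariant and intensity metrics scale-invariant", {
  ph0 <- make_structural(small_spec(noise_sigma = 0))
  ph5 <- make_structural(small_spec(noise_sigma = 0,
                                    center_offset_mm = c(5, 0, 0)))
  cm0 <- center_of_mass(ph0$volume, ph0$brain_mask)
  cm5 <- center_of_mass(ph5$volume, ph5$brain_mask)
  expect_equal(cm5$offset_mm[["x"]] - cm0$offset_mm[["x"]], 5,
               tolerance = 1)                    # within half a voxel

  ph <- make_structural(small_spec(seed = 33))
  r1 <- structural_report(ph$volume, fwhm_min_voxels = 500L)
  scaled <- qc_volume(ph$volume$values * 3.7,
                      voxel_size = ph$volume$voxel_size)
  r2 <- structural_report(scaled, fwhm_min_voxels = 500L)
  expect_equal(r1$scalars, r2$scalars, tolerance = 1e-9)
  expect_equal(r1$fwhm$fwhm, r2$fwhm$fwhm, tolerance = 1e-9)
  expect_equal(r1$com$offset_mm, r2$com$offset_mm)
})

test_that("rising background noise monotonically degrades SNR and CNR", {
  sigmas <- c(2, 4, 6, 8, 10)
  means <- sapply(sigmas, function(sg) {
    vals <- vapply(1:3, function(s) {
      ph <- make_structural(small_spec(noise_sigma = sg,
                                       noise_type = "gaussian",
                                       seed = 100 * sg + s))
      st <- tissue_stats(ph$volume,
                         truth_partition(ph$head_mask, ph$brain_mask),
                         ph$labels)
      c(compute_snr(st), compute_cnr(st))
    }, numeric(2))
    rowMeans(vals)
  })
  expect_equal(unname(cor(sigmas, means[1, ], method = "spearman")), -1)
  expect_equal(unname(cor(sigmas, means[2, ], method = "spearman")), -1)
})

test_that("odd-even slice difference uses 0-based slice parity", {
  vals <- array(0, c(8, 8, 10))
  for (k in 1:10) vals[, , k] <- if ((k - 1) %% 2 == 0) 20 else 10
  expect_equal(odd_even_slice_difference(qc_volume(vals)), -10)
  expect_equal(odd_even_slice_difference(qc_volume(array(7.7, c(8, 8, 8)) +
    array(0, c(8, 8, 8)))), 0)

  set.seed(306)
  vals2 <- array(rnorm(8 * 8 * 12), c(8, 8, 12))
  msi <- vapply(1:12, function(k) mean(vals2[, , k]), numeric(1))
  oracle <- mean(msi[seq(2, 12, 2)]) - mean(msi[seq(1, 12, 2)])
  expect_equal(odd_even_slice_difference(qc_volume(vals2)), oracle,
               tolerance = 1e-12)
})

test_that("structural report composes profiles and is deterministic", {
  ph <- make_structural(small_spec(seed = 34))
  r <- structural_report(ph$volume, fwhm_min_voxels = 500L)
  expect_true(all(is.finite(r$scalars)))
  expect_true(all(is.finite(r$fwhm$fwhm)))
  expect_true(is.finite(r$com$magnitude))
  expect_length(r$msi, 32)

  rct <- structural_report(ph$volume, profile = "ct",
                           fwhm_min_voxels = 500L)
  expect_equal(unname(rct$flags[c("cnr", "cvnr", "tctv")]),
               rep("unavailable", 3))
  expect_equal(unname(rct$flags[c("snr", "svnr", "msi", "com")]),
               rep("ok", 4))
  expect_true(is.na(rct$scalars[["cnr"]]))

  rph <- structural_report(ph$volume, profile = "phantom",
                           fwhm_min_voxels = 500L)
  expect_true(is.numeric(rph$odd_even_difference))

  r2 <- structural_report(ph$volume, fwhm_min_voxels = 500L)
  expect_identical(r$scalars, r2$scalars)
  expect_identical(r$fwhm, r2$fwhm)
})
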