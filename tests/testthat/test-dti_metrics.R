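dti_fixture <- function(noise_sigma = 0, seed = 1,
                        shape = c(24, 24, 16)) {
  scheme <- default_dti_scheme()
  spec <- phantom_spec(shape = shape, voxel_size = c(2, 2, 2),
                       noise_sigma = noise_sigma, seed = seed)
  list(scheme = scheme, ph = make_diffusion(spec, scheme))
}

test_that("per-gradient metrics centre CoM displacements at zero", {
  fx <- dti_fixture()
  part <- truth_partition(fx$ph$head_mask, fx$ph$brain_mask)
  pg <- per_gradient_metrics(fx$ph$series, fx$scheme, part)

  # mean-centring: displacements sum to zero per axis
  expect_lt(max(abs(colSums(pg$com_displacement))), 1e-9)

  # MSI equals the brute-force frame mean
  oracle <- vapply(seq_len(n_frames(fx$ph$series)), function(t)
    mean(fx$ph$series$values[, , , t]), numeric(1))
  expect_equal(pg$msi, oracle, tolerance = 1e-12)

  # identical frames: all displacements zero
  arr <- array(rep(fx$ph$series$values[, , , 1], 4), c(24, 24, 16, 4))
  s <- qc_series(arr, voxel_size = c(2, 2, 2))
  sch <- qc_gradients(c(0, 1000, 1000, 1000),
                      cbind(0, diag(3))[, c(1, 2, 3, 4)])
  pg0 <- per_gradient_metrics(s, sch, part)
  expect_equal(max(abs(pg0$com_displacement)), 0)
})

test_that("a shifted frame shows the mean-centring arithmetic", {
  # 11 static frames, one shifted by +2 mm in y
  d <- c(24, 24, 16); vs <- c(2, 2, 2)
  base <- scanqc:::ellipsoid_r2(d, vs, (d - 1) / 2 * vs,
                                c(14, 16, 12)) <= 1
  arr <- array(0, c(d, 11))
  for (t in 1:11) arr[, , , t] <- base * 100
  shifted <- scanqc:::ellipsoid_r2(d, vs, (d - 1) / 2 * vs + c(0, 2, 0),
                                   c(14, 16, 12)) <= 1
  arr[, , , 6] <- shifted * 100
  s <- qc_series(arr, voxel_size = vs)
  sch <- qc_gradients(c(0, rep(1000, 10)),
                      cbind(0, default_dti_scheme()$directions[, 3:12]))
  part <- truth_partition(base)
  pg <- per_gradient_metrics(s, sch, part)
  expect_equal(unname(pg$com_displacement[6, "y"]), 2 * 10 / 11,
               tolerance = 0.15)
  expect_equal(unname(pg$com_displacement[1, "y"]), -2 / 11,
               tolerance = 0.15)
})

test_that("gradient histograms integrate the masked intensities", {
  fx <- dti_fixture()
  h <- gradient_histograms(fx$ph$series, fx$scheme, fx$ph$head_mask)
  expect_length(h, 14L)
  x1 <- fx$ph$series$values[, , , 1][fx$ph$head_mask]
  expect_equal(sum(h[[1]]$counts), length(x1))
  expect_equal(unname(h[[1]]$stats["mean"]), mean(x1), tolerance = 1e-12)
  expect_equal(unname(h[[1]]$stats["sd"]), sd_pop_oracle(x1),
               tolerance = 1e-12)
  expect_equal(unname(h[[1]]$stats[c("min", "max")]), range(x1))

  # constant volume: one occupied bin, zero SD
  arr <- array(5, c(8, 8, 8, 2))
  s <- qc_series(arr)
  sch <- qc_gradients(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
  hc <- gradient_histograms(s, sch, array(TRUE, c(8, 8, 8)))
  expect_equal(sum(hc[[1]]$counts > 0), 1L)
  expect_equal(unname(hc[[1]]$stats["sd"]), 0)

  expect_error(gradient_histograms(s, sch, array(FALSE, c(8, 8, 8))),
               "empty")
})

test_that("tensor fits recover known diagonal tensors analytically", {
  fx <- dti_fixture()
  fit <- fit_tensor(fx$ph$series, fx$scheme, fx$ph$compartments == 4L)

  lam <- c(1.7e-3, 0.2e-3, 0.2e-3)
  md <- mean(lam)
  fa <- sqrt(1.5) * sqrt(sum((lam - md)^2)) / sqrt(sum(lam^2))
  expect_lt(max(abs(fit$fa_map - fa), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(fit$md_map - md), na.rm = TRUE), 1e-9)

  # isotropic compartment: FA = 0, MD exact, ADC = MD
  fit_gm <- fit_tensor(fx$ph$series, fx$scheme, fx$ph$compartments == 3L)
  expect_lt(max(fit_gm$fa_map, na.rm = TRUE), 1e-9)
  expect_lt(max(abs(fit_gm$md_map - 0.8e-3), na.rm = TRUE), 1e-12)
  expect_lt(max(abs(fit_gm$adc_map - 0.8e-3), na.rm = TRUE), 1e-12)
  expect_false(any(fit_gm$negative_eigenvalue_mask))
})

test_that("single-gradient ADC equals -log(S/S0)/b", {
  d <- c(8, 8, 8)
  arr <- array(0, c(d, 8))
  s0 <- 400; adc <- 1.1e-3; b <- 1000
  arr[, , , 1] <- s0
  dirs <- default_dti_scheme()$directions[, 3:9]
  for (t in 2:8) arr[, , , t] <- s0 * exp(-b * adc)
  sch <- qc_gradients(c(0, rep(b, 7)), cbind(0, dirs))
  fit <- fit_tensor(qc_series(arr), sch, array(TRUE, d))
  expect_equal(unique(round(as.vector(fit$adc_map), 12)),
               round(-log(exp(-b * adc)) / b, 12))
})

test_that("collinear gradient designs are rejected by condition number", {
  d <- c(8, 8, 8)
  arr <- array(100, c(d, 8))
  g <- matrix(rep(c(1, 0, 0), 7), 3)            # all x-direction
  sch <- qc_gradients(c(0, rep(1000, 7)), cbind(0, g))
  expect_error(fit_tensor(qc_series(arr), sch, array(TRUE, d)),
               "condition number")
  sch6 <- qc_gradients(c(0, rep(1000, 5)),
                       cbind(0, default_dti_scheme()$directions[, 3:7]))
  expect_error(fit_tensor(qc_series(array(100, c(d, 6))), sch6,
                          array(TRUE, d)), ">= 6")
})

test_that("Rician noise keeps FA bounded and MD bias small", {
  fx <- dti_fixture(noise_sigma = 20, seed = 9)   # b0 WM signal 440, SNR ~22
  fit <- fit_tensor(fx$ph$series, fx$scheme, fx$ph$compartments == 4L)
  fa <- fit$fa_map[is.finite(fit$fa_map)]
  expect_true(all(fa >= 0 & fa <= 1))
  md <- median(fit$md_map, na.rm = TRUE)
  expect_lt(abs(md - 0.7e-3) / 0.7e-3, 0.05)
})

test_that("the slice report is a complete per-gradient-and-slice table", {
  fx <- dti_fixture()
  tab <- slice_report(fx$ph$series, fx$scheme, mask = fx$ph$head_mask)
  expect_equal(nrow(tab), 14L * 16L)
  expect_named(tab, c("gradient", "slice", "n_voxels", "mean", "sd",
                      "min", "max"))

  sl <- fx$ph$series$values[, , 8, 3][fx$ph$head_mask[, , 8]]
  row <- tab[tab$gradient == 3 & tab$slice == 8, ]
  expect_equal(row$n_voxels, length(sl))
  expect_equal(row$mean, mean(sl), tolerance = 1e-12)
  expect_equal(row$sd, sd_pop_oracle(sl), tolerance = 1e-12)

  # slices outside the head are empty but present
  empty <- tab[tab$slice == 1, ]
  expect_true(all(empty$n_voxels == 0))
  expect_true(all(is.na(empty$mean)))
})

test_that("the composed diffusion report runs end to end", {
  fx <- dti_fixture(noise_sigma = 5, seed = 11)
  rep <- diffusion_report(fx$ph$series, fx$scheme)
  expect_s3_class(rep, "qc_diffusion_metrics")
  expect_length(rep$per_gradient$msi, 14L)
  expect_false(is.null(rep$tensor))
  expect_true(all(rep$tensor$fa_map >= 0 & rep$tensor$fa_map <= 1,
                  na.rm = TRUE))
})
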