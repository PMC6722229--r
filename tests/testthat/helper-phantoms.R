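# shared fixtures, built in code at test time

dice_masks <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small structural phantom (fast default for unit tests)
small_spec <- function(...) {
  phantom_spec(shape = c(32, 32, 32), voxel_size = c(2, 2, 2), ...)
}

# hand-built tissue stats object for formula tests
fake_stats <- function(mu_head = NA, sd_background = NA, var_head = NA,
                       var_background = NA, mu_gm = NA, mu_wm = NA,
                       sd_gm = NA, sd_wm = NA) {
  structure(list(mu_head = mu_head, sd_head = NA_real_,
                 var_head = var_head, sd_background = sd_background,
                 var_background = var_background,
                 mu_gm = mu_gm, mu_wm = mu_wm, mu_csf = NA_real_,
                 sd_gm = sd_gm, sd_wm = sd_wm, sd_csf = NA_real_,
                 n_brain_voxels = 1000L, tissues_available = TRUE),
            class = "qc_tissue_stats")
}

# partition object from ground-truth masks (bypasses the quantile rule)
truth_partition <- function(head_mask, brain_mask = NULL) {
  structure(list(head_mask = head_mask, background_mask = !head_mask,
                 brain_mask = brain_mask),
            class = "qc_partition")
}

# population SD oracle
sd_pop_oracle <- function(x) sqrt(mean((x - mean(x))^2))
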