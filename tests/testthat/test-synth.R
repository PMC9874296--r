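test_that("MRI phantom signal follows the mono-exponential model exactly", {
  ph <- make_mri_phantom(noise_sd = 0, seed = 1,
                         lesion_params = list(T2 = 80, M0 = 1000,
                                              radius_mm = 1.5),
                         background_params = list(T2 = 30, M0 = 1000))
  lesion <- ph$truth$lesion_mask$mask
  expect_true(any(lesion))
  # voxel at lesion center, first echo (TE = 7 ms): closed form
  idx <- which(lesion, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  s <- ph$volume$data[ctr[1], ctr[2], ctr[3], 1]
  expect_equal(s, 1000 * exp(-7 / 80), tolerance = 1e-12)
  # background limb voxel decays with T2 = 30
  bg <- which(ph$truth$limb_left$mask, arr.ind = TRUE)[1, ]
  expect_equal(ph$volume$data[bg[1], bg[2], bg[3], 4],
               1000 * exp(-28 / 30), tolerance = 1e-12)
})

test_that("MRI phantom geometry: lesion confined to right limb, volume bookkeeping", {
  ph <- make_mri_phantom(spacing = rep(0.234, 3), noise_sd = 0, seed = 2,
                         lesion_params = list(T2 = 80, M0 = 1000,
                                              radius_mm = 0.702))
  tr <- ph$truth
  expect_true(all(!tr$lesion_mask$mask | tr$limb_right$mask))
  expect_false(any(tr$lesion_mask$mask & tr$limb_left$mask))
  expect_false(any(tr$limb_left$mask & tr$limb_right$mask))
  # truth volume equals brute-force voxel count x voxel volume
  n <- sum(tr$lesion_mask$mask)
  expect_equal(tr$lesion_volume_mm3, n * 0.234^3)
  # radius of 3 voxel edges: count must match the rasterized ball around
  # the voxel nearest the sphere center (independent re-count)
  idx <- which(tr$lesion_mask$mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  d <- sqrt(rowSums((sweep(idx, 2, ctr))^2))
  expect_true(all(d <= 3 + 1))  # all mask voxels within radius + 1 shell
})

test_that("MRI phantom is reproducible under a fixed seed and validates inputs", {
  a <- make_mri_phantom(noise_sd = 5, seed = 42)
  b <- make_mri_phantom(noise_sd = 5, seed = 42)
  expect_identical(a$volume$data, b$volume$data)
  c <- make_mri_phantom(noise_sd = 5, seed = 43)
  expect_false(identical(a$volume$data, c$volume$data))
  expect_error(make_mri_phantom(lesion_params = list(T2 = -5, M0 = 1000,
                                                     radius_mm = 1)),
               "positive")
  expect_error(make_mri_phantom(
    lesion_params = list(T2 = 30, M0 = 1000, radius_mm = 1),
    background_params = list(T2 = 30, M0 = 1000)), "differ")
})

test_that("PET phantom decay scaling and dose bookkeeping are exact", {
  p0 <- make_pet_phantom(injection_to_scan_min = 0, seed = 1)
  ph <- make_pet_phantom(injection_to_scan_min = 109.77,
                         half_life_min = 109.77, seed = 1)
  # one half-life: every voxel exactly halved relative to no decay
  expect_equal(ph$acquisition$activity$data, p0$acquisition$activity$data / 2,
               tolerance = 1e-12)
  # truth uptake integrates to the in-phantom dose fraction
  vox_ml <- prod(p0$truth$limb_left$spacing) / 1000
  expect_equal(sum(p0$truth$uptake_fraction_per_ml) * vox_ml,
               p0$truth$in_phantom_fraction, tolerance = 1e-9)
  expect_error(make_pet_phantom(uptake_params = list(
    lesion_fraction = 0.7, node_fraction = 0.4, background_fraction = 0.2,
    lesion_radius_mm = 3, node_radius_mm = 1.5)), "sum")
})

test_that("cell table draws intensities from the phenotype's mixture components", {
  sim <- make_cell_table(n_cells = 10000, seed = 7)
  truth <- sim$truth
  # empirical CD20-positive fraction within 3 binomial SDs of truth
  p <- truth$positive_fraction[["CD20"]]
  m <- truth$mixtures[truth$mixtures$channel == "CD20", ]
  cut <- (m$neg_mean + m$pos_mean) / 2
  emp <- mean(sim$cells$CD20 > cut)
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / 10000) + 1e-3)
  # reproducibility
  sim2 <- make_cell_table(n_cells = 10000, seed = 7)
  expect_identical(sim$cells, sim2$cells)
  # contradictory phenotype rules rejected at definition time
  expect_error(phenotype_definition("bad", "CD3", "CD3"), "both")
  # phenotypes referencing unsimulated channels rejected
  expect_error(make_cell_table(
    n_cells = 100,
    phenotypes = list(phenotype_definition("x", "CD99")),
    phenotype_fractions = c(x = 1), channels = "CD3"), "unsimulated")
})

test_that("follicular geometry places FDCs at follicle centers", {
  sim <- make_cell_table(n_cells = 5000, follicle_sd_um = 25, seed = 3)
  lab <- sim$truth$phenotype
  cen <- sim$truth$follicle_centers[sim$truth$follicle_of, , drop = FALSE]
  d <- sqrt((sim$cells$x_um - cen[, "x"])^2 +
              (sim$cells$y_um - cen[, "y"])^2)
  # FDCs hug the centers much tighter than uniform cell types
  expect_lt(median(d[lab == "follicular_dendritic_cell"]),
            median(d[lab == "macrophage"]) / 3)
  expect_lt(median(d[lab == "follicular_B_cell"]), 4 * 25)
})

test_that("endpoint curves: zero noise reproduces the group mean, AUC scales with amplitude", {
  ser <- make_endpoint_series(groups = c("A", "B"), peak_amplitude = c(4.3, 1),
                              baseline = 0, noise_cv = 0, seed = 1)
  truth <- attr(ser, "truth")
  for (g in c("A", "B")) {
    sub <- ser[ser$group == g, ]
    for (s in unique(sub$subject_id)) {
      expect_equal(sub$value[sub$subject_id == s],
                   unname(truth$mean_curves[[g]]), tolerance = 1e-12)
    }
  }
  auc_a <- auc_trapezoid(ser$time_hr[ser$subject_id == "R001"],
                         ser$value[ser$subject_id == "R001"])
  auc_b <- auc_trapezoid(ser$time_hr[ser$subject_id == "R005"],
                         ser$value[ser$subject_id == "R005"])
  expect_equal(auc_a / auc_b, 4.3, tolerance = 1e-9)
  expect_error(make_endpoint_series(timepoints = c(4, 24)), "baseline")
})

test_that("log-AUC ANOVA detects a 4-fold group difference at study noise", {
  # Monte-Carlo power check over simulated replicates
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    ser <- make_endpoint_series(groups = c("hi", "lo"), n_per_group = 8,
                                peak_amplitude = c(4, 1), baseline = 0.25,
                                noise_cv = 0.2, seed = 10000 + r)
    aucs <- endpoint_auc(ser)
    res <- anova_log_tukey(aucs$auc, aucs$group)
    if (res$p_value[1] < 0.01) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.9)
})
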