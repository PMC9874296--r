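make_small_table <- function(n = 60, seed = 1) {
  make_cell_table(n_cells = n, seed = seed)$cells
}

test_that("z-normalisation centers and scales each channel (population SD)", {
  tab <- make_small_table(200)
  z <- znormalize(tab)
  for (ch in cell_channels(tab)) {
    zc <- z[[paste0("z_", ch)]]
    expect_lt(abs(mean(zc)), 1e-9)
    expect_lt(abs(sqrt(mean(zc^2)) - 1), 1e-9)
    expect_true(ch %in% colnames(z))  # raw intensities retained
  }
  # two-point channel {0, 2}: z = {-1, +1} under the population convention
  tiny <- data.frame(cell_id = 1:2, sample_id = "s", roi_id = "r",
                     x_um = c(0, 1), y_um = c(0, 1), area_um2 = c(1, 1),
                     CD3 = c(0, 2))
  expect_equal(znormalize(tiny)$z_CD3, c(-1, 1))
  # a single outlier owns the largest |z|
  tab2 <- tab
  tab2$CD3[5] <- max(tab2$CD3) + 100
  z2 <- znormalize(tab2)
  expect_equal(which.max(abs(z2$z_CD3)), 5L)
  # zero-variance channel errors, naming the channel
  tab3 <- tab; tab3$CD3 <- 1
  expect_error(znormalize(tab3), "CD3")
})

test_that("mixture gating recovers a well-separated positive population", {
  set.seed(5)
  n <- 5000
  truth_pos <- runif(n) < 0.3
  x <- ifelse(truth_pos, rnorm(n, 3, 0.5), rnorm(n, -0.5, 0.5))
  g <- gate_channel(x, seed = 2)
  expect_gt(mean((g$positive) == truth_pos), 0.99)
  phat <- mean(g$positive)
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_lt(g$means[1], g$means[2])
  expect_equal(sum(g$weights), 1, tolerance = 1e-6)
  expect_false(g$degenerate)
})

test_that("gating contracts: degenerate input, mirror symmetry, determinism", {
  expect_error(gate_channel(rep(1, 100)), "identical")
  expect_error(gate_channel(rnorm(5)), "at least")
  set.seed(6)
  x <- c(rnorm(500, -0.5, 0.4), rnorm(300, 3, 0.6))
  g1 <- gate_channel(x, seed = 3)
  g2 <- gate_channel(-x, seed = 3)
  # mirrored data: the same cells are called, on the flipped component
  expect_equal(g1$positive, !g2$positive)
  g3 <- gate_channel(x, seed = 3)
  expect_identical(g1$positive, g3$positive)
  expect_identical(g1$means, g3$means)
  # equal-mean scale mixture: components coincide in mean -> warning
  set.seed(7)
  xd <- c(rnorm(1000, 0, 1), rnorm(1000, 0, 5))
  expect_warning(gate_channel(xd, seed = 1), "coincide")
})

test_that("K-means clustering separates spherical clusters and is deterministic", {
  set.seed(8)
  n <- 400
  truth <- rep(1:2, each = n / 2)
  tab <- data.frame(cell_id = 1:n, sample_id = "s", roi_id = "r",
                    x_um = runif(n), y_um = runif(n), area_um2 = 1,
                    A = rnorm(n, ifelse(truth == 1, 0, 8), 0.5),
                    B = rnorm(n, ifelse(truth == 1, 8, 0), 0.5))
  tab <- znormalize(tab)
  cl <- cluster_cells(tab, k = 2, seed = 4)
  expect_gt(adjusted_rand_index(cl$cluster_id, truth), 0.99)
  cl2 <- cluster_cells(tab, k = 2, seed = 4)
  expect_identical(cl$cluster_id, cl2$cluster_id)
  # k = number of cells: every cell its own cluster, zero inertia
  sm <- znormalize(tab[1:8, ])
  cls <- cluster_cells(sm, k = 8, seed = 1)
  expect_equal(length(unique(cls$cluster_id)), 8)
  expect_error(cluster_cells(sm, k = 9, seed = 1), "exceeds")
})

test_that("cluster phenotype assignment follows the canonical marker rules", {
  # two clusters built by hand: pure CD21+CD20- and all-negative
  n <- 40
  tab <- data.frame(cell_id = 1:n, sample_id = "s", roi_id = "r",
                    x_um = runif(n), y_um = runif(n), area_um2 = 1,
                    CD21 = 0, CD20 = 0)
  tab$cluster_id <- rep(1:2, each = n / 2)
  tab$pos_CD21 <- tab$cluster_id == 1
  tab$pos_CD20 <- FALSE
  defs <- list(phenotype_definition("follicular_dendritic_cell",
                                    "CD21", "CD20"))
  out <- assign_phenotypes(tab, defs)
  expect_true(all(out$phenotype[out$cluster_id == 1] ==
                    "follicular_dendritic_cell"))
  expect_true(all(out$phenotype[out$cluster_id == 2] == "unassigned"))
  # equal explicit priorities that both match must error
  defs2 <- list(phenotype_definition("a", "CD21", priority = 1),
                phenotype_definition("b", "CD21", priority = 1))
  expect_error(assign_phenotypes(tab, defs2), "priority")
})

test_that("end-to-end phenotyping recovers simulated truth", {
  sim <- make_cell_table(n_cells = 3000, seed = 12)
  tab <- znormalize(sim$cells)
  tab <- gate_cells(tab, seed = 13)
  tab <- cluster_cells(tab, k = 15, seed = 14, n_init = 5)
  tab <- assign_phenotypes(tab)
  acc <- mean(tab$phenotype == sim$truth$phenotype)
  expect_gt(acc, 0.95)
  ratios <- cell_type_ratio(tab)
  # per-sample ratios sum to 1 including unassigned
  expect_equal(sum(ratios$ratio), 1, tolerance = 1e-12)
  truth_frac <- sim$truth$phenotype_fractions
  for (p in names(truth_frac)) {
    got <- ratios$ratio[ratios$phenotype == p]
    expect_lt(abs(got - truth_frac[[p]]), 0.03)
  }
})

test_that("cell-type ratios are conserved and invariant to ROI splitting", {
  sim <- make_cell_table(n_cells = 500, seed = 20)
  tab <- znormalize(sim$cells)
  tab <- gate_cells(tab, seed = 21)
  tab <- cluster_cells(tab, k = 12, seed = 22, n_init = 3)
  tab <- assign_phenotypes(tab)
  r1 <- cell_type_ratio(tab)
  # split the sample into two ROIs: per-sample aggregation unchanged
  tab2 <- tab
  tab2$roi_id <- rep(c("R1", "R2"), length.out = nrow(tab2))
  r2 <- cell_type_ratio(tab2)
  expect_equal(r1$ratio, r2$ratio)
  expect_equal(sum(r1$ratio), 1, tolerance = 1e-12)
  # single-phenotype sample
  one <- tab[tab$phenotype == tab$phenotype[1], ]
  ro <- cell_type_ratio(one, phenotypes = c(tab$phenotype[1], "other"))
  expect_equal(ro$ratio[1], 1)
  expect_equal(ro$ratio[2], 0)
  expect_error(cell_type_ratio(tab[0, ]), "empty")
})
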