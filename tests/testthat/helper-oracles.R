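# Independent brute-force oracles and small fixtures used across tests.
# These deliberately use naive loops, not the package's vectorised paths.

# Sum of squared intensities: explicit per-voxel loop collecting terms.
oracle_energy <- function(data, mask) {
  idx <- which(mask, arr.ind = TRUE)
  terms <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    terms[r] <- data[idx[r, 1], idx[r, 2], idx[r, 3]]^2
  }
  sum(terms)
}

# GLDM dependence non-uniformity by explicit per-voxel neighbour loops.
oracle_dnu <- function(data, mask, n_bins, alpha = 0, connectivity = 26) {
  v <- data[mask]
  rng <- range(v)
  g <- array(NA_integer_, dim(mask))
  if (rng[1] == rng[2]) {
    g[mask] <- 1L
  } else {
    b <- floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
    g[mask] <- pmin(b, n_bins)
  }
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, ]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, ]
  d3 <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  deps <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    d <- 0L
    for (o in seq_len(nrow(off))) {
      ii <- i + off$dx[o]; jj <- j + off$dy[o]; kk <- k + off$dz[o]
      if (ii < 1 || ii > d3[1] || jj < 1 || jj > d3[2] ||
          kk < 1 || kk > d3[3]) next
      if (!mask[ii, jj, kk]) next
      if (abs(g[i, j, k] - g[ii, jj, kk]) <= alpha) d <- d + 1L
    }
    deps[r] <- d
  }
  counts <- table(deps)
  sum(as.numeric(counts)^2) / length(deps)
}

# Mean count of B cells within radius of each A cell, O(n^2) loops.
oracle_proximity <- function(ax, ay, bx, by, radius, same = FALSE) {
  counts <- numeric(length(ax))
  for (i in seq_along(ax)) {
    c0 <- 0L
    for (j in seq_along(bx)) {
      if (same && i == j) next
      if (sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2) <= radius) {
        c0 <- c0 + 1L
      }
    }
    counts[i] <- c0
  }
  mean(counts)
}

# Median nearest-neighbour distance, O(n^2) loops.
oracle_nn <- function(ax, ay, bx, by, same = FALSE) {
  nn <- numeric(length(ax))
  for (i in seq_along(ax)) {
    best <- Inf
    for (j in seq_along(bx)) {
      if (same && i == j) next
      d <- sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2)
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  median(nn)
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Minimal phenotyped cell table for the spatial metrics.
spatial_table <- function(x, y, phenotype, sample_id = "S1") {
  data.frame(cell_id = seq_along(x), sample_id = sample_id, roi_id = "R1",
             x_um = x, y_um = y, phenotype = phenotype,
             stringsAsFactors = FALSE)
}

# Search slab: right-limb voxels on the z-slices the lesion touches.
lesion_slab_mask <- function(truth) {
  zs <- unique(which(truth$lesion_mask$mask, arr.ind = TRUE)[, 3])
  m <- truth$limb_right$mask
  m[, , setdiff(seq_len(dim(m)[3]), zs)] <- FALSE
  roi_mask(m, truth$limb_right$spacing, "lesion_slab")
}
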