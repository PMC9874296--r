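#' Radiomics feature set
#'
#' The three image features carried forward from the study's feature
#' screen: first-order energy, first-order interquartile range, and the
#' gray level dependence matrix (GLDM) dependence non-uniformity (DNU),
#' together with correlation-threshold univariate feature selection.
#'
#' @name radiomics
NULL

roi_values <- function(vol, roi) {
  stopifnot(inherits(vol, "scalar_volume"))
  check_same_geometry(vol, roi)
  if (!any(roi$mask)) stop("ROI is empty")
  vol$data[roi$mask]
}

#' First-order energy
#'
#' Sum of squared in-mask intensities.
#'
#' @param vol a [scalar_volume].
#' @param roi a non-empty [roi_mask].
#' @return The energy value (intensity^2 units).
#' @export
first_order_energy <- function(vol, roi) {
  v <- roi_values(vol, roi)
  sum(v^2)
}

#' First-order interquartile range
#'
#' 75th minus 25th percentile of in-mask intensities, using the
#' linear-interpolation percentile definition (`stats::quantile` type 7).
#'
#' @param vol a [scalar_volume].
#' @param roi a [roi_mask] with at least 4 in-mask voxels.
#' @return The IQR in intensity units.
#' @export
first_order_iqr <- function(vol, roi) {
  v <- roi_values(vol, roi)
  if (length(v) < 4L) stop("IQR requires at least 4 in-mask voxels")
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

# Equal-width discretization over the in-ROI min-max range.
discretize_bins <- function(v, n_bins) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(1L, length(v)))
  g <- floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  pmin(g, n_bins)
}

neighbor_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) {
    off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  } else if (connectivity == 18) {
    off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  } else if (connectivity != 26) {
    stop("connectivity must be 6, 18 or 26")
  }
  off
}

#' GLDM dependence non-uniformity
#'
#' Intensities inside the ROI are discretized into `n_bins` equal-width
#' bins over the in-ROI min-max range. Each voxel's dependence is the
#' number of its neighbours (within `connectivity`, restricted to the ROI;
#' neighbours outside the ROI are ignored) whose gray level differs by at
#' most `alpha`. With `P(g, d)` the count of voxels at gray level `g` and
#' dependence `d`,
#' `DNU = sum_d ( sum_g P(g, d) )^2 / N_voxels`,
#' which grows when voxels concentrate at few dependence values
#' (homogeneous texture) and is 1 for a single-voxel ROI.
#'
#' @param vol a [scalar_volume].
#' @param roi a non-empty [roi_mask].
#' @param n_bins number of gray-level bins (>= 2; default 32).
#' @param alpha dependence tolerance on the binned gray level (default 0).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return The DNU value.
#' @export
gldm_dnu <- function(vol, roi, n_bins = 32, alpha = 0, connectivity = 26) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  v <- roi_values(vol, roi)
  d3 <- dim(roi$mask)

  g <- array(NA_integer_, d3)
  g[roi$mask] <- discretize_bins(v, n_bins)

  dep <- array(0L, d3)
  off <- neighbor_offsets(connectivity)
  ix <- seq_len(d3[1]); iy <- seq_len(d3[2]); iz <- seq_len(d3[3])
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    sx <- ix[ix + o[1] >= 1 & ix + o[1] <= d3[1]]
    sy <- iy[iy + o[2] >= 1 & iy + o[2] <= d3[2]]
    sz <- iz[iz + o[3] >= 1 & iz + o[3] <= d3[3]]
    a <- g[sx, sy, sz, drop = FALSE]
    b <- g[sx + o[1], sy + o[2], sz + o[3], drop = FALSE]
    hit <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    dep[sx, sy, sz] <- as.vector(dep[sx, sy, sz]) + as.vector(hit)
  }

  dv <- dep[roi$mask]
  nd <- table(dv)            # collapses over gray levels: sum_g P(g, d)
  sum(as.numeric(nd)^2) / length(dv)
}

#' Correlation-threshold univariate feature selection
#'
#' Computes the Pearson correlation of every feature column with the
#' outcome and returns the features whose `|r|` meets the threshold,
#' ranked by `|r|` descending. Constant features have undefined
#' correlation and are dropped with a message.
#'
#' @param features numeric matrix or data.frame, samples x features, with
#'   column names.
#' @param outcome numeric vector, one value per sample; must not be
#'   constant.
#' @param threshold minimum `|r|` to retain a feature (default 0.7).
#' @return A data.frame with columns `feature`, `r`, `abs_r`, `p_value`,
#'   sorted by `abs_r` descending.
#' @export
correlate_features <- function(features, outcome, threshold = 0.7) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("feature_", seq_len(ncol(features)))
  }
  if (nrow(features) != length(outcome)) {
    stop("features has ", nrow(features), " rows but outcome has ",
         length(outcome), " values")
  }
  if (nrow(features) < 3L) stop("at least 3 samples are required")
  if (stats::sd(outcome) == 0) stop("outcome is constant")

  keep <- apply(features, 2, stats::sd) > 0
  if (any(!keep)) {
    message("dropping ", sum(!keep), " constant feature(s): ",
            paste(colnames(features)[!keep], collapse = ", "))
  }
  features <- features[, keep, drop = FALSE]
  res <- lapply(colnames(features), function(f) {
    ct <- stats::cor.test(features[, f], outcome, method = "pearson")
    data.frame(feature = f, r = unname(ct$estimate),
               abs_r = abs(unname(ct$estimate)),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[res$abs_r >= threshold, , drop = FALSE]
  res <- res[order(-res$abs_r), , drop = FALSE]
  rownames(res) <- NULL
  res
}
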