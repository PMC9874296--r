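#' T2 relaxometry and enhancement volumetry
#'
#' Per-voxel mono-exponential T2/M0 estimation from a multi-slice
#' multi-echo acquisition, the contralateral mean + k*SD enhancement
#' threshold, and ROI summary statistics.
#'
#' @name mri
NULL

#' Fit per-voxel T2 and M0 parameter maps
#'
#' Fits the mono-exponential decay `S(TE) = M0 * exp(-TE / T2)` at each
#' voxel of a multi-echo stack. The default `log_linear` method is ordinary
#' unweighted least squares of `log S` on TE (slope = -1/T2); `nonlinear`
#' refines the log-linear estimate by Levenberg-Marquardt least squares on
#' the exponential model itself.
#'
#' Voxels with any echo at or below `min_signal` are flagged invalid
#' (`NA` in both maps) rather than clipped: the log transform is undefined
#' there and low-signal voxels are noise-dominated air. A voxel whose
#' signal does not decay (fitted slope >= 0, e.g. constant signal) has no
#' finite relaxation time; its T2 is flagged `Inf` and its M0 set to the
#' geometric mean signal.
#'
#' @param vol a [multi_echo_volume].
#' @param method `"log_linear"` (default) or `"nonlinear"`.
#' @param min_signal signal floor in a.u.; voxels with any echo <=
#'   this value are excluded from fitting.
#' @return A list with `t2` (a [scalar_volume], ms) and `m0`
#'   (a [scalar_volume], a.u.).
#' @export
fit_t2_map <- function(vol, method = c("log_linear", "nonlinear"),
                       min_signal = 0) {
  method <- match.arg(method)
  stopifnot(inherits(vol, "multi_echo_volume"))
  te <- vol$echo_times
  if (length(te) < 2L) stop("at least two echoes are required")
  d <- dim(vol$data)
  nvox <- prod(d[1:3])
  sig <- matrix(vol$data, nrow = nvox, ncol = d[4])

  valid <- rowSums(sig <= min_signal | !is.finite(sig)) == 0L
  if (!any(valid)) stop("no voxel has all echoes above min_signal; empty fit")

  t2 <- rep(NA_real_, nvox)
  m0 <- rep(NA_real_, nvox)

  # closed-form OLS of log(signal) on TE, vectorised over voxels
  ls <- log(sig[valid, , drop = FALSE])
  tbar <- mean(te)
  sxx <- sum((te - tbar)^2)
  slope <- as.vector(ls %*% (te - tbar)) / sxx
  inter <- rowMeans(ls) - slope * tbar
  t2v <- ifelse(slope < 0, -1 / slope, Inf)
  m0v <- exp(inter)

  if (method == "nonlinear") {
    if (!requireNamespace("minpack.lm", quietly = TRUE)) {
      stop("method 'nonlinear' requires the minpack.lm package")
    }
    idx <- which(is.finite(t2v))
    sv <- sig[valid, , drop = FALSE]
    for (k in idx) {
      y <- sv[k, ]
      fit <- try(minpack.lm::nlsLM(
        y ~ m * exp(-te / t), start = list(m = m0v[k], t = t2v[k]),
        lower = c(1e-12, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
        silent = TRUE)
      if (!inherits(fit, "try-error")) {
        cf <- stats::coef(fit)
        m0v[k] <- cf[["m"]]
        t2v[k] <- cf[["t"]]
      }
    }
  }

  t2[valid] <- t2v
  m0[valid] <- m0v
  list(t2 = scalar_volume(array(t2, d[1:3]), vol$spacing, unit = "ms"),
       m0 = scalar_volume(array(m0, d[1:3]), vol$spacing, unit = "a.u."))
}

#' Threshold-based signal-enhancement mask and volume
#'
#' Reproduces contralateral-control enhancement volumetry: the threshold is
#' the mean + `k_sd` * SD of the control-ROI voxels (population SD), and
#' the enhancement mask contains the voxels of the search ROI whose value
#' is strictly greater than that threshold. The comparison is strict, so
#' ties at exactly the threshold are excluded.
#'
#' @param vol a [scalar_volume] (typically the T2-weighted image).
#' @param control_roi [roi_mask] over the contralateral control region;
#'   must be non-empty and disjoint from `search_roi`.
#' @param search_roi [roi_mask] over the region searched for enhancement.
#' @param k_sd number of control SDs above the control mean (default 2).
#' @return A list with `mask` (a [roi_mask]), `volume_mm3`, `threshold`,
#'   `control_mean` and `control_sd`.
#' @export
enhancement_mask <- function(vol, control_roi, search_roi, k_sd = 2) {
  stopifnot(inherits(vol, "scalar_volume"))
  check_same_geometry(vol, control_roi)
  check_same_geometry(vol, search_roi)
  if (!any(control_roi$mask)) stop("control ROI is empty")
  if (!any(search_roi$mask)) stop("search ROI is empty")
  if (any(control_roi$mask & search_roi$mask)) {
    stop("control and search ROIs must be disjoint")
  }
  cv <- vol$data[control_roi$mask]
  mu <- mean(cv)
  sdp <- sqrt(mean((cv - mu)^2))  # population SD
  thr <- mu + k_sd * sdp
  m <- search_roi$mask & (vol$data > thr)
  list(mask = roi_mask(m, vol$spacing,
                       paste0(search_roi$label, "_enhancement")),
       volume_mm3 = sum(m) * voxel_volume_mm3(vol),
       threshold = thr, control_mean = mu, control_sd = sdp)
}

#' ROI summary statistics
#'
#' Mean, SD (sample), volume and voxel count of a scalar volume over a
#' region of interest; used for lymph-node volume and mean-T2 readouts.
#'
#' @param vol a [scalar_volume].
#' @param roi a non-empty [roi_mask] with matching geometry.
#' @param na.rm drop flagged-invalid (`NA`) voxels inside the ROI.
#' @return A list with `mean`, `sd`, `volume_mm3`, `voxel_count`.
#' @export
roi_stats <- function(vol, roi, na.rm = TRUE) {
  stopifnot(inherits(vol, "scalar_volume"))
  check_same_geometry(vol, roi)
  if (!any(roi$mask)) stop("ROI '", roi$label, "' is empty")
  v <- vol$data[roi$mask]
  if (na.rm) v <- v[is.finite(v)]
  if (!length(v)) stop("ROI '", roi$label, "' has no finite voxels")
  list(mean = mean(v), sd = stats::sd(v),
       volume_mm3 = sum(roi$mask) * voxel_volume_mm3(vol),
       voxel_count = sum(roi$mask))
}
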