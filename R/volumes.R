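#' Volumetric containers
#'
#' Lightweight S3 containers for the voxel data moved between pipeline
#' stages: a 3-D scalar volume with a unit tag, a 4-D multi-echo stack with
#' its echo times, and a boolean region-of-interest mask. Spacing is always
#' millimetres per voxel edge, stored as a length-3 numeric `(x, y, z)`.
#'
#' @name volumes
NULL

#' Create a scalar volume
#'
#' @param data numeric 3-D array of voxel values.
#' @param spacing numeric length-3, voxel spacing in mm (must be > 0).
#' @param unit unit tag, e.g. `"ms"`, `"a.u."`, `"%ID/g"`, `"HU"`,
#'   `"activity/mL"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing, unit = "a.u.") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("scalar_volume data must be a 3-D array")
  spacing <- check_spacing(spacing)
  structure(list(data = data, spacing = spacing, unit = unit),
            class = "scalar_volume")
}

#' Create a multi-echo volume
#'
#' @param data numeric 4-D array indexed `[x, y, z, echo]`, signal in a.u.
#' @param echo_times numeric vector of echo times in ms, strictly
#'   increasing, one per echo.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return An object of class `multi_echo_volume`.
#' @export
multi_echo_volume <- function(data, echo_times, spacing) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) {
    stop("multi_echo_volume data must be a 4-D array [x, y, z, echo]")
  }
  echo_times <- as.numeric(echo_times)
  if (dim(data)[4] != length(echo_times)) {
    stop("echo dimension (", dim(data)[4], ") does not match number of ",
         "echo times (", length(echo_times), ")")
  }
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0)) {
    stop("echo_times must be positive and strictly increasing")
  }
  spacing <- check_spacing(spacing)
  structure(list(data = data, echo_times = echo_times, spacing = spacing),
            class = "multi_echo_volume")
}

#' Create a region-of-interest mask
#'
#' @param mask logical 3-D array (or 0/1 numeric, coerced).
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param label text label describing the region.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, spacing, label = "roi") {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("roi_mask must be a 3-D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("roi_mask may not contain NA")
  spacing <- check_spacing(spacing)
  structure(list(mask = mask, spacing = spacing, label = label),
            class = "roi_mask")
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive values (mm)")
  }
  spacing
}

#' Voxel volume in cubic millimetres
#' @param x a `scalar_volume`, `multi_echo_volume` or `roi_mask`.
#' @return Volume of one voxel in mm^3.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

check_same_geometry <- function(vol, roi) {
  dv <- dim(vol$data)[1:3]
  dm <- dim(roi$mask)
  if (!all(dv == dm)) {
    stop("volume (", paste(dv, collapse = "x"), ") and mask (",
         paste(dm, collapse = "x"), ") shapes differ")
  }
  if (max(abs(vol$spacing - roi$spacing)) > 1e-9) {
    stop("volume and mask voxel spacing differ")
  }
  invisible(TRUE)
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, unit ", x$unit, "\n", sep = "")
  invisible(x)
}

#' @export
print.multi_echo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<multi_echo_volume> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " echoes (TE ", min(x$echo_times), "-", max(x$echo_times),
      " ms), spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> '", x$label, "': ", sum(x$mask), " of ",
      length(x$mask), " voxels (",
      signif(sum(x$mask) * prod(x$spacing), 5), " mm^3)\n", sep = "")
  invisible(x)
}
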