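#' PET quantification
#'
#' Decay correction to injection time, conversion of activity concentration
#' to percent injected dose per gram (%ID/g, assuming tissue density
#' 1 g/mL), baseline-referenced enhancement volumetry, and total uptake
#' (glycolytic burden) as mean %ID/g times enhancement volume.
#'
#' @name pet
NULL

#' Fluorine-18 half-life in minutes
#' @export
F18_HALF_LIFE_MIN <- 109.77

#' Create a PET acquisition record
#'
#' @param activity a [scalar_volume] of measured activity concentration
#'   (activity units per mL) at scan time.
#' @param injected_dose net injected activity, same activity unit.
#' @param injection_time,scan_time minutes; `scan_time >= injection_time`.
#' @param half_life isotope half-life in minutes (default fluorine-18).
#' @return An object of class `pet_acquisition`.
#' @export
pet_acquisition <- function(activity, injected_dose, injection_time = 0,
                            scan_time = 0, half_life = F18_HALF_LIFE_MIN) {
  stopifnot(inherits(activity, "scalar_volume"))
  if (injected_dose <= 0) stop("injected_dose must be > 0")
  if (half_life <= 0) stop("half_life must be > 0")
  if (scan_time < injection_time) stop("scan_time must be >= injection_time")
  structure(list(activity = activity, injected_dose = injected_dose,
                 injection_time = injection_time, scan_time = scan_time,
                 half_life = half_life),
            class = "pet_acquisition")
}

#' @export
print.pet_acquisition <- function(x, ...) {
  cat("<pet_acquisition> dose ", x$injected_dose, ", dt ",
      x$scan_time - x$injection_time, " min, T1/2 ", x$half_life, " min\n",
      sep = "")
  print(x$activity)
  invisible(x)
}

#' Decay-correct measured activity to injection time
#'
#' Multiplies every voxel by `2^((scan_time - injection_time) / half_life)`
#' so the returned concentration refers to the activity at injection.
#'
#' @param acq a [pet_acquisition].
#' @return A [scalar_volume] of decay-corrected activity concentration.
#' @export
decay_correct <- function(acq) {
  stopifnot(inherits(acq, "pet_acquisition"))
  dt <- acq$scan_time - acq$injection_time
  f <- 2^(dt / acq$half_life)
  scalar_volume(acq$activity$data * f, acq$activity$spacing,
                unit = acq$activity$unit)
}

#' Convert activity concentration to %ID/g
#'
#' `100 * concentration / injected_dose`, with tissue density taken as
#' 1 g/mL so activity per millilitre equals activity per gram.
#'
#' @param corrected decay-corrected [scalar_volume] (activity per mL).
#' @param injected_dose net injected dose in the same activity unit.
#' @return A [scalar_volume] in %ID/g.
#' @export
percent_id_per_g <- function(corrected, injected_dose) {
  stopifnot(inherits(corrected, "scalar_volume"))
  if (injected_dose <= 0) stop("injected_dose must be > 0")
  scalar_volume(100 * corrected$data / injected_dose, corrected$spacing,
                unit = "%ID/g")
}

#' PET enhancement volume above a baseline threshold
#'
#' Voxels of the search ROI strictly above `baseline_mean + k_sd *
#' baseline_sd`. The baseline statistics come from the baseline-timepoint
#' scan over the same anatomical ROI and are supplied by the caller.
#'
#' @param vol a [scalar_volume] (%ID/g or activity).
#' @param baseline_mean,baseline_sd baseline statistics; `baseline_sd >= 0`.
#' @param search_roi non-empty [roi_mask].
#' @param k_sd number of SDs (default 2).
#' @return A list with `mask`, `volume_mm3` and `threshold`.
#' @export
pet_enhancement_volume <- function(vol, baseline_mean, baseline_sd,
                                   search_roi, k_sd = 2) {
  stopifnot(inherits(vol, "scalar_volume"))
  check_same_geometry(vol, search_roi)
  if (!any(search_roi$mask)) stop("search ROI is empty")
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  thr <- baseline_mean + k_sd * baseline_sd
  m <- search_roi$mask & (vol$data > thr)
  list(mask = roi_mask(m, vol$spacing,
                       paste0(search_roi$label, "_enhancement")),
       volume_mm3 = sum(m) * voxel_volume_mm3(vol),
       threshold = thr)
}

#' Total uptake (glycolytic burden)
#'
#' Mean %ID/g within the enhancement mask multiplied by the enhancement
#' volume; units %ID.mm^3/g.
#'
#' @param mean_idg mean %ID/g over the enhancement mask (>= 0).
#' @param enhancement_volume_mm3 enhancement volume in mm^3 (>= 0).
#' @return The product, in %ID.mm^3/g.
#' @export
total_uptake <- function(mean_idg, enhancement_volume_mm3) {
  if (mean_idg < 0 || enhancement_volume_mm3 < 0) {
    stop("mean %ID/g and volume must be non-negative")
  }
  mean_idg * enhancement_volume_mm3
}
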