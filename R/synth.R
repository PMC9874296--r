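#' Synthetic data generators
#'
#' Every downstream stage of the pipeline is exercised against data from
#' these generators, which carry full ground truth: bilateral-limb MR
#' phantoms with a unilateral high-T2 lesion, static PET acquisitions with a
#' known injected dose and uptake hot spots, lymph-node cell tables with
#' follicular spatial structure and bimodal marker intensities, and peaked
#' temporal endpoint curves with multiplicative noise.
#'
#' All generators are bit-reproducible under a fixed seed, and setting the
#' noise parameters to zero makes the downstream estimators exact up to
#' floating point.
#'
#' @name synth
NULL

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  code
}

# World coordinate (mm) of each voxel center along one axis, 0-based.
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

# Rasterized sphere: voxels whose centers lie within radius_mm of center_mm.
sphere_mask <- function(shape, spacing, center_mm, radius_mm) {
  cx <- axis_coords(shape[1], spacing[1])
  cy <- axis_coords(shape[2], spacing[2])
  cz <- axis_coords(shape[3], spacing[3])
  dx2 <- (cx - center_mm[1])^2
  dy2 <- (cy - center_mm[2])^2
  dz2 <- (cz - center_mm[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(d2 <= radius_mm^2, dim = shape)
}

# Axis-aligned cylinder along z, circular cross-section in the x-y plane.
cylinder_mask <- function(shape, spacing, center_xy_mm, radius_mm) {
  cx <- axis_coords(shape[1], spacing[1])
  cy <- axis_coords(shape[2], spacing[2])
  d2 <- outer((cx - center_xy_mm[1])^2, (cy - center_xy_mm[2])^2, `+`)
  array(rep(d2 <= radius_mm^2, shape[3]), dim = shape)
}

#' Simulate a bilateral-limb multi-echo MR phantom
#'
#' Two disjoint axis-aligned cylinders stand in for the left and right
#' hindlimb; a spherical high-T2 lesion sits inside the right limb only, and
#' an optional small sphere stands in for a draining lymph node. The
#' noiseless voxel signal follows the mono-exponential decay
#' `S(TE) = M0 * exp(-TE / T2)` of each compartment; noise is additive
#' Gaussian by default (Rician optional via `noise_model`).
#'
#' @param shape integer length-3 voxel grid (x, y, z).
#' @param spacing voxel spacing in mm.
#' @param echo_times echo times in ms; the default eight-echo train runs
#'   TE = 7, 14, ..., 56 ms.
#' @param lesion_params list with `T2` (ms), `M0` (a.u.), `radius_mm`, and
#'   optionally `center_frac_z` (axial position as a fraction of the grid).
#' @param background_params list with `T2` (ms) and `M0` (a.u.) for limb
#'   tissue outside the lesion.
#' @param node_params optional list (`T2`, `M0`, `radius_mm`) for a
#'   lymph-node sphere in the right limb; `NULL` to omit.
#' @param noise_sd standard deviation of the additive noise, in signal a.u.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param seed integer RNG seed.
#' @return A list with `volume` (a [multi_echo_volume]) and `truth`, a
#'   `phantom_truth` record holding the compartment masks
#'   (`lesion_mask`, `limb_left`, `limb_right`, `node_mask`), the true T2/M0
#'   per compartment, `lesion_volume_mm3`, `noise_sd` and `seed`.
#' @export
make_mri_phantom <- function(shape = c(48L, 48L, 12L),
                             spacing = c(0.234, 0.234, 1.5),
                             echo_times = seq(7, 56, by = 7),
                             lesion_params = list(T2 = 80, M0 = 1000,
                                                  radius_mm = 1.5),
                             background_params = list(T2 = 30, M0 = 1000),
                             node_params = NULL,
                             noise_sd = 0,
                             noise_model = c("gaussian", "rician"),
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  spacing <- check_spacing(spacing)
  echo_times <- as.numeric(echo_times)
  for (p in list(lesion_params$T2, lesion_params$M0,
                 background_params$T2, background_params$M0,
                 node_params$T2, node_params$M0)) {
    if (!is.null(p) && (!is.finite(p) || p <= 0)) {
      stop("T2 and M0 parameters must be strictly positive")
    }
  }
  if (lesion_params$T2 == background_params$T2) {
    stop("lesion T2 must differ from background T2")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  fov <- shape * spacing
  limb_r <- 0.18 * fov[1]
  left <- cylinder_mask(shape, spacing, c(0.25 * fov[1], 0.5 * fov[2]), limb_r)
  right <- cylinder_mask(shape, spacing, c(0.75 * fov[1], 0.5 * fov[2]), limb_r)

  zc <- lesion_params$center_frac_z %||% 0.5
  lesion_center <- c(0.75 * fov[1], 0.5 * fov[2], zc * fov[3])
  lesion <- sphere_mask(shape, spacing, lesion_center, lesion_params$radius_mm)
  lesion <- lesion & right

  node <- array(FALSE, shape)
  if (!is.null(node_params)) {
    # inside the right limb, offset from the lesion towards the popliteal side
    node_center <- c(0.75 * fov[1], 0.5 * fov[2] + 0.55 * limb_r,
                     (node_params$center_frac_z %||% 0.5) * fov[3])
    node <- sphere_mask(shape, spacing, node_center, node_params$radius_mm)
    node <- node & right & !lesion
    if (!any(node)) stop("lymph-node sphere does not fit inside the limb; ",
                         "reduce node radius")
  }

  t2 <- array(NA_real_, shape)
  m0 <- array(0, shape)
  tissue <- (left | right) & !lesion & !node
  t2[tissue] <- background_params$T2
  m0[tissue] <- background_params$M0
  t2[lesion] <- lesion_params$T2
  m0[lesion] <- lesion_params$M0
  if (any(node)) {
    t2[node] <- node_params$T2
    m0[node] <- node_params$M0
  }

  data <- array(0, c(shape, length(echo_times)))
  for (e in seq_along(echo_times)) {
    s <- ifelse(is.na(t2), 0, m0 * exp(-echo_times[e] / t2))
    data[, , , e] <- s
  }
  if (noise_sd > 0) {
    data <- with_seed(seed, {
      if (noise_model == "gaussian") {
        data + array(stats::rnorm(length(data), sd = noise_sd), dim(data))
      } else {
        n1 <- array(stats::rnorm(length(data), sd = noise_sd), dim(data))
        n2 <- array(stats::rnorm(length(data), sd = noise_sd), dim(data))
        sqrt((data + n1)^2 + n2^2)
      }
    })
  }

  vol <- multi_echo_volume(data, echo_times, spacing)
  truth <- structure(list(
    lesion_mask = roi_mask(lesion, spacing, "lesion"),
    limb_left = roi_mask(left, spacing, "limb_left"),
    limb_right = roi_mask(right, spacing, "limb_right"),
    node_mask = roi_mask(node, spacing, "lymph_node"),
    lesion_T2 = lesion_params$T2, background_T2 = background_params$T2,
    lesion_M0 = lesion_params$M0, background_M0 = background_params$M0,
    node_T2 = node_params$T2, node_M0 = node_params$M0,
    lesion_volume_mm3 = sum(lesion) * prod(spacing),
    noise_sd = noise_sd, noise_model = noise_model, seed = seed
  ), class = "phantom_truth")
  list(volume = vol, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a static PET acquisition with known uptake
#'
#' Builds a true uptake map in fraction of injected dose per mL -- a hot
#' spherical lesion in the right limb, a hot lymph-node spot, and a low
#' uniform background over both limbs -- then scales it to the measured
#' activity concentration at scan time through the radioactive decay factor
#' `2^-(scan - injection)/T_half`, so that decay correction can be verified
#' against truth. The default half-life is the fluorine-18 value, 109.77 min.
#'
#' @param shape,spacing voxel grid and spacing (mm); defaults mimic an
#'   0.66 mm isotropic small-animal reconstruction.
#' @param injected_dose net injected activity (any fixed unit, e.g. uCi).
#' @param injection_to_scan_min minutes between injection and scan start.
#' @param half_life_min isotope half-life in minutes.
#' @param uptake_params list of dose fractions `lesion_fraction`,
#'   `node_fraction`, `background_fraction` (spread over both limbs) and
#'   radii `lesion_radius_mm`, `node_radius_mm`; fractions must sum to <= 1.
#' @param noise_sd additive Gaussian noise sd on the measured activity
#'   concentration (same unit per mL); 0 for noiseless.
#' @param seed integer RNG seed.
#' @return A list with `acquisition` (a [pet_acquisition]) and `truth`
#'   holding the uptake-fraction map (per mL), the compartment masks, the
#'   in-phantom dose fraction, and the geometry.
#' @export
make_pet_phantom <- function(shape = c(48L, 48L, 24L),
                             spacing = c(0.66, 0.66, 0.66),
                             injected_dose = 400,
                             injection_to_scan_min = 60,
                             half_life_min = 109.77,
                             uptake_params = list(lesion_fraction = 0.05,
                                                  node_fraction = 0.01,
                                                  background_fraction = 0.10,
                                                  lesion_radius_mm = 3,
                                                  node_radius_mm = 1.5),
                             noise_sd = 0,
                             seed = 1L) {
  shape <- as.integer(shape)
  spacing <- check_spacing(spacing)
  if (injected_dose <= 0) stop("injected_dose must be > 0")
  if (half_life_min <= 0) stop("half_life_min must be > 0")
  if (injection_to_scan_min < 0) stop("injection_to_scan_min must be >= 0")
  fr <- c(uptake_params$lesion_fraction, uptake_params$node_fraction,
          uptake_params$background_fraction)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("uptake fractions must be non-negative and sum to <= 1")
  }

  fov <- shape * spacing
  limb_r <- 0.18 * fov[1]
  left <- cylinder_mask(shape, spacing, c(0.25 * fov[1], 0.5 * fov[2]), limb_r)
  right <- cylinder_mask(shape, spacing, c(0.75 * fov[1], 0.5 * fov[2]), limb_r)
  lesion <- sphere_mask(shape, spacing,
                        c(0.75 * fov[1], 0.5 * fov[2], 0.5 * fov[3]),
                        uptake_params$lesion_radius_mm) & right
  node <- sphere_mask(shape, spacing,
                      c(0.75 * fov[1], 0.5 * fov[2] + 0.55 * limb_r,
                        0.75 * fov[3]),
                      uptake_params$node_radius_mm) & right & !lesion
  if (uptake_params$node_fraction > 0 && !any(node)) {
    stop("lymph-node spot does not fit inside the limb; reduce node radius")
  }

  vox_ml <- prod(spacing) / 1000  # mm^3 -> mL
  uptake <- array(0, shape)      # fraction of dose per mL
  bg <- (left | right) & !lesion & !node
  uptake[bg] <- uptake_params$background_fraction / (sum(bg) * vox_ml)
  uptake[lesion] <- uptake_params$lesion_fraction / (sum(lesion) * vox_ml)
  if (any(node)) {
    uptake[node] <- uptake_params$node_fraction / (sum(node) * vox_ml)
  }

  decay <- 2^(-injection_to_scan_min / half_life_min)
  activity <- injected_dose * uptake * decay
  if (noise_sd > 0) {
    activity <- with_seed(seed, {
      activity + array(stats::rnorm(length(activity), sd = noise_sd),
                       dim(activity))
    })
  }

  acq <- pet_acquisition(
    activity = scalar_volume(activity, spacing, unit = "activity/mL"),
    injected_dose = injected_dose,
    injection_time = 0,
    scan_time = injection_to_scan_min,
    half_life = half_life_min
  )
  truth <- structure(list(
    uptake_fraction_per_ml = uptake,
    lesion_mask = roi_mask(lesion, spacing, "lesion"),
    node_mask = roi_mask(node, spacing, "lymph_node"),
    limb_left = roi_mask(left, spacing, "limb_left"),
    limb_right = roi_mask(right, spacing, "limb_right"),
    lesion_fraction = uptake_params$lesion_fraction,
    node_fraction = uptake_params$node_fraction,
    background_fraction = uptake_params$background_fraction,
    in_phantom_fraction = sum(fr),
    lesion_volume_mm3 = sum(lesion) * prod(spacing),
    noise_sd = noise_sd, seed = seed
  ), class = "phantom_truth")
  list(acquisition = acq, truth = truth)
}

#' Default channel mixture parameters for simulated cell tables
#'
#' Raw per-cell mean intensities (arbitrary units) are drawn from a
#' two-component Gaussian: a non-expressing component and a well separated
#' expressing component, as seen after spillover-compensated IMC
#' acquisition.
#'
#' @param channels character vector of channel names.
#' @param neg_mean,neg_sd,pos_mean,pos_sd component parameters, recycled
#'   across channels.
#' @return A data.frame with one row per channel.
#' @export
default_channel_mixtures <- function(channels,
                                     neg_mean = 1, neg_sd = 0.4,
                                     pos_mean = 6, pos_sd = 1) {
  data.frame(channel = channels,
             neg_mean = rep_len(neg_mean, length(channels)),
             neg_sd = rep_len(neg_sd, length(channels)),
             pos_mean = rep_len(pos_mean, length(channels)),
             pos_sd = rep_len(pos_sd, length(channels)),
             stringsAsFactors = FALSE)
}

#' Simulate a lymph-node single-cell table with follicular structure
#'
#' Each simulated cell gets exactly one true phenotype drawn from
#' `phenotype_fractions`; its per-channel intensity is drawn from the
#' positive mixture component for the channels in that phenotype's marker
#' signature and from the negative component otherwise. Follicular
#' dendritic cells sit at follicle centers, follicular B cells disperse
#' around them, and all other phenotypes scatter uniformly over the field,
#' mimicking B-cell follicle organisation in a stained section.
#'
#' @param n_cells number of cells to simulate.
#' @param phenotypes list of [phenotype_definition]s; defaults to
#'   [default_phenotypes()]. The marker signature of a phenotype is its
#'   `required_positive` set; all other simulated channels are negative.
#' @param phenotype_fractions named numeric vector of true phenotype
#'   proportions (summing to 1); names must match the definitions.
#' @param channels channel names; defaults to the union of markers used by
#'   `phenotypes`.
#' @param mixtures per-channel mixture parameters as from
#'   [default_channel_mixtures()].
#' @param field_um field of view (width = height) in micrometres.
#' @param n_follicles number of follicles.
#' @param follicle_sd_um dispersion (sd, µm) of follicular B cells around
#'   their follicle center; FDCs use a quarter of this.
#' @param sample_id,roi_id labels written into the table.
#' @param seed integer RNG seed.
#' @return A list with `cells` (the cell table, one row per cell, columns
#'   `cell_id, sample_id, roi_id, x_um, y_um, area_um2, <channel>...`) and
#'   `truth` holding per-cell phenotype labels, follicle centers, the
#'   mixture parameters, and the per-channel true positive fraction.
#' @export
make_cell_table <- function(n_cells = 10000,
                            phenotypes = default_phenotypes(),
                            phenotype_fractions = default_phenotype_fractions(),
                            channels = NULL,
                            mixtures = NULL,
                            field_um = 1000,
                            n_follicles = 5,
                            follicle_sd_um = 30,
                            sample_id = "S1",
                            roi_id = "ROI1",
                            seed = 1L) {
  stopifnot(n_cells >= 1)
  names_def <- vapply(phenotypes, function(p) p$name, character(1))
  if (is.null(names(phenotype_fractions)) ||
      !all(names(phenotype_fractions) %in% names_def)) {
    stop("phenotype_fractions must be named after the phenotype definitions")
  }
  if (abs(sum(phenotype_fractions) - 1) > 1e-8) {
    stop("phenotype_fractions must sum to 1")
  }
  if (is.null(channels)) {
    channels <- sort(unique(unlist(lapply(phenotypes, function(p)
      c(p$required_positive, p$required_negative)))))
  }
  for (p in phenotypes) {
    bad <- setdiff(c(p$required_positive, p$required_negative), channels)
    if (length(bad)) {
      stop("phenotype '", p$name, "' references unsimulated channel(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (is.null(mixtures)) mixtures <- default_channel_mixtures(channels)
  if (any(mixtures$pos_mean <= mixtures$neg_mean)) {
    stop("every channel's positive mean must exceed its negative mean")
  }
  sig <- lapply(phenotypes, function(p) p$required_positive)
  names(sig) <- names_def

  with_seed(seed, {
    labels <- sample(names(phenotype_fractions), n_cells, replace = TRUE,
                     prob = phenotype_fractions)
    centers <- cbind(x = stats::runif(n_follicles, 0.2, 0.8) * field_um,
                     y = stats::runif(n_follicles, 0.2, 0.8) * field_um)
    x <- stats::runif(n_cells, 0, field_um)
    y <- stats::runif(n_cells, 0, field_um)
    is_fdc <- labels == "follicular_dendritic_cell"
    is_folb <- labels == "follicular_B_cell"
    foll_of <- sample.int(n_follicles, n_cells, replace = TRUE)
    place <- function(idx, sd_um) {
      n <- sum(idx)
      x[idx] <<- pmin(pmax(centers[foll_of[idx], "x"] +
                             stats::rnorm(n, sd = sd_um), 0), field_um)
      y[idx] <<- pmin(pmax(centers[foll_of[idx], "y"] +
                             stats::rnorm(n, sd = sd_um), 0), field_um)
    }
    place(is_fdc, follicle_sd_um / 4)
    place(is_folb, follicle_sd_um)

    inten <- matrix(NA_real_, n_cells, length(channels),
                    dimnames = list(NULL, channels))
    for (j in seq_along(channels)) {
      ch <- channels[j]
      pos <- vapply(labels, function(l) ch %in% sig[[l]], logical(1))
      m <- mixtures[mixtures$channel == ch, ]
      inten[, j] <- ifelse(pos,
                           stats::rnorm(n_cells, m$pos_mean, m$pos_sd),
                           stats::rnorm(n_cells, m$neg_mean, m$neg_sd))
    }
    pos_frac <- vapply(channels, function(ch) {
      mean(vapply(labels, function(l) ch %in% sig[[l]], logical(1)))
    }, numeric(1))

    cells <- data.frame(cell_id = seq_len(n_cells),
                        sample_id = sample_id, roi_id = roi_id,
                        x_um = x, y_um = y,
                        area_um2 = stats::rlnorm(n_cells,
                                                 meanlog = log(80), sdlog = 0.3),
                        stringsAsFactors = FALSE)
    cells <- cbind(cells, as.data.frame(inten))
    truth <- structure(list(
      phenotype = labels, follicle_centers = centers,
      follicle_of = foll_of, follicle_sd_um = follicle_sd_um,
      mixtures = mixtures, positive_fraction = pos_frac,
      phenotype_fractions = phenotype_fractions, seed = seed
    ), class = "cell_sim_truth")
    list(cells = cells, truth = truth)
  })
}

#' Default true phenotype composition for simulated lymph nodes
#' @return Named numeric vector of phenotype proportions summing to 1.
#' @export
default_phenotype_fractions <- function() {
  c(follicular_dendritic_cell = 0.05,
    follicular_B_cell = 0.25,
    B_cell = 0.15,
    helper_T_cell = 0.15,
    cytotoxic_T_cell = 0.10,
    T_follicular_helper = 0.05,
    regulatory_T_cell = 0.05,
    macrophage = 0.08,
    antigen_presenting_cell = 0.12)
}

#' Simulate temporal endpoint curves
#'
#' Each group's mean response over time is a log-normal-shaped pulse rising
#' from baseline to `peak_amplitude` at `peak_time` hours; per-subject
#' values are the group mean multiplied by lognormal noise with unit mean
#' and coefficient of variation `noise_cv`. At the baseline timepoint
#' (0 hr) the mean equals `baseline`.
#'
#' @param groups character vector of treatment labels.
#' @param cohorts character vector of cohort labels (e.g. Prime,
#'   PrimeBoost); the design is fully crossed groups x cohorts.
#' @param n_per_group subjects per (group, cohort) cell.
#' @param timepoints hours; must include 0 (baseline).
#' @param peak_time hour of the mean peak, per group (recycled).
#' @param peak_amplitude peak mean height above baseline, per group
#'   (recycled across groups, applied in all cohorts).
#' @param baseline mean baseline level (endpoint units, > 0).
#' @param pulse_width width (sd on the log-time scale) of the pulse.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `subject_id, group, cohort, time_hr,
#'   value` and an attribute `truth` holding the noiseless group mean
#'   curves.
#' @export
make_endpoint_series <- function(groups = c("AS01", "SAM"),
                                 cohorts = "Prime",
                                 n_per_group = 4,
                                 timepoints = c(0, 4, 24, 48, 72),
                                 peak_time = 24,
                                 peak_amplitude = c(4, 1),
                                 baseline = 1,
                                 pulse_width = 0.8,
                                 noise_cv = 0.2,
                                 seed = 1L) {
  if (!0 %in% timepoints) stop("timepoints must include 0 (baseline)")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (baseline < 0) stop("baseline must be >= 0")
  timepoints <- sort(unique(as.numeric(timepoints)))
  amp <- rep_len(peak_amplitude, length(groups))
  pk <- rep_len(peak_time, length(groups))
  names(amp) <- names(pk) <- groups

  mean_curve <- function(g, t) {
    ifelse(t <= 0, baseline,
           baseline + amp[g] * exp(-(log(t / pk[g]))^2 / (2 * pulse_width^2)))
  }

  with_seed(seed, {
    rows <- list()
    sdlog <- sqrt(log(1 + noise_cv^2))
    sid <- 0L
    for (co in cohorts) for (g in groups) for (i in seq_len(n_per_group)) {
      sid <- sid + 1L
      mu <- mean_curve(g, timepoints)
      noise <- if (noise_cv > 0) {
        stats::rlnorm(length(timepoints), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, length(timepoints))
      rows[[sid]] <- data.frame(
        subject_id = sprintf("R%03d", sid), group = g, cohort = co,
        time_hr = timepoints, value = mu * noise,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    truth <- lapply(stats::setNames(groups, groups), mean_curve, t = timepoints)
    attr(out, "truth") <- list(mean_curves = truth, timepoints = timepoints,
                               baseline = baseline, peak_time = pk,
                               peak_amplitude = amp, noise_cv = noise_cv,
                               seed = seed)
    out
  })
}
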