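#' End-to-end synthetic demonstration pipeline
#'
#' Runs every stage against the synthetic generators under one
#' configuration: phantom simulation, T2 mapping and enhancement
#' volumetry, PET quantification, radiomics features, the IMC single-cell
#' pipeline with spatial metrics, and the endpoint statistics. All
#' randomness flows from the configuration's top-level seed (each stage
#' receives a seed derived from it by a fixed offset), so rerunning the
#' same configuration reproduces every numeric output bit-identically.
#'
#' @param config configuration list, see [default_config()].
#' @param out_dir optional directory; when given, results and a JSON
#'   manifest (inputs, seeds, parameters, package version) are written
#'   there.
#' @return A list of per-stage result bundles plus `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stage_seed <- function(offset) {
    as.integer((as.numeric(config$seed) + offset) %% (.Machine$integer.max - 1))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seeds <- list(mri = stage_seed(101), pet = stage_seed(202),
                imc = stage_seed(303), endpoints = stage_seed(404),
                gating = stage_seed(505), clustering = stage_seed(606))

  ## --- MRI ---------------------------------------------------------------
  cm <- config$mri
  mri_res <- run_stage("mri", {
    ph <- make_mri_phantom(
      shape = cm$shape, spacing = cm$spacing, echo_times = cm$echo_times,
      lesion_params = list(T2 = cm$lesion_T2, M0 = cm$lesion_M0,
                           radius_mm = cm$lesion_radius_mm),
      background_params = list(T2 = cm$background_T2, M0 = cm$background_M0),
      noise_sd = cm$noise_sd, seed = seeds$mri)
    maps <- fit_t2_map(ph$volume, method = cm$fit_method,
                       min_signal = cm$min_signal)
    enh <- enhancement_mask(maps$t2, ph$truth$limb_left,
                            ph$truth$limb_right, k_sd = cm$k_sd)
    lesion_stats <- roi_stats(maps$t2, ph$truth$lesion_mask)
    list(truth = ph$truth, t2 = maps$t2, m0 = maps$m0,
         enhancement = enh, lesion_t2_stats = lesion_stats)
  })

  ## --- PET ---------------------------------------------------------------
  cp <- config$pet
  pet_res <- run_stage("pet", {
    ph <- make_pet_phantom(
      shape = cp$shape, spacing = cp$spacing,
      injected_dose = cp$injected_dose,
      injection_to_scan_min = cp$injection_to_scan_min,
      half_life_min = cp$half_life_min,
      uptake_params = list(lesion_fraction = cp$lesion_fraction,
                           node_fraction = cp$node_fraction,
                           background_fraction = cp$background_fraction,
                           lesion_radius_mm = cp$lesion_radius_mm,
                           node_radius_mm = cp$node_radius_mm),
      seed = seeds$pet)
    corrected <- decay_correct(ph$acquisition)
    idg <- percent_id_per_g(corrected, ph$acquisition$injected_dose)
    base <- roi_stats(idg, ph$truth$limb_left)
    enh <- pet_enhancement_volume(idg, base$mean, base$sd,
                                  ph$truth$limb_right, k_sd = cp$k_sd)
    mean_idg <- roi_stats(idg, enh$mask)$mean
    list(truth = ph$truth, idg = idg, enhancement = enh,
         mean_idg = mean_idg,
         total_uptake = total_uptake(mean_idg, enh$volume_mm3))
  })

  ## --- Radiomics ---------------------------------------------------------
  rad_res <- run_stage("radiomics", {
    nb <- config$radiomics$n_bins
    list(
      pet_energy = first_order_energy(pet_res$idg,
                                      pet_res$truth$limb_right),
      t2_iqr = first_order_iqr(mri_res$t2, mri_res$truth$limb_right),
      m0_dnu = gldm_dnu(mri_res$m0, mri_res$enhancement$mask,
                        n_bins = nb),
      n_bins = nb)
  })

  ## --- IMC + spatial -----------------------------------------------------
  ci <- config$imc
  imc_res <- run_stage("imc", {
    samples <- list()
    truths <- list()
    group_of <- list()
    idx <- 0L
    for (g in ci$groups) {
      sd_um <- ci$follicle_sd_um[[g]]
      for (r in seq_len(ci$n_samples_per_group)) {
        idx <- idx + 1L
        sid <- sprintf("%s_%02d", g, r)
        sim <- make_cell_table(n_cells = ci$n_cells,
                               follicle_sd_um = sd_um,
                               sample_id = sid,
                               seed = stage_seed(303 + idx))
        samples[[sid]] <- sim$cells
        truths[[sid]] <- sim$truth
        group_of[[sid]] <- g
      }
    }
    out <- list()
    metrics <- list()
    for (sid in names(samples)) {
      tab <- znormalize(samples[[sid]])
      tab <- gate_cells(tab, seed = seeds$gating)
      tab <- cluster_cells(tab, k = ci$k, seed = seeds$clustering,
                           n_init = ci$n_init)
      tab <- assign_phenotypes(tab)
      out[[sid]] <- tab
      prox <- proximity_count(tab, "follicular_dendritic_cell",
                              "follicular_B_cell",
                              radius_um = config$spatial$radius_um)
      nn <- nearest_neighbor_distance(tab, "follicular_dendritic_cell",
                                      "follicular_B_cell")
      metrics[[sid]] <- data.frame(
        sample_id = sid, group = group_of[[sid]],
        proximity = prox$value, nn_distance = nn$value,
        stringsAsFactors = FALSE)
    }
    all_cells <- do.call(rbind, out)
    ratios <- cell_type_ratio(all_cells)
    ratios$group <- unlist(group_of)[ratios$sample_id]
    list(tables = out, truths = truths, ratios = ratios,
         spatial = do.call(rbind, metrics))
  })

  ## --- Statistics --------------------------------------------------------
  ce <- config$endpoints
  stats_res <- run_stage("stats", {
    series <- make_endpoint_series(
      groups = ce$groups, cohorts = ce$cohorts,
      n_per_group = ce$n_per_group, timepoints = ce$timepoints,
      peak_time = ce$peak_time, peak_amplitude = ce$peak_amplitude,
      baseline = ce$baseline, noise_cv = ce$noise_cv,
      seed = seeds$endpoints)
    aucs <- endpoint_auc(series)
    peaks <- group_max(series)
    anova_auc <- anova_log_tukey(aucs$auc, aucs$group)
    folb <- imc_res$ratios[imc_res$ratios$phenotype == "follicular_B_cell", ]
    beta_folb <- beta_regression(folb$ratio, folb$group)
    sp <- imc_res$spatial
    prox_lm <- transformed_lm(sp$proximity, sp$group, transform = "sqrt")
    nn_lm <- transformed_lm(sp$nn_distance, sp$group, transform = "log")
    list(series = series, auc = aucs, peaks = peaks,
         anova_auc = anova_auc, beta_folb = beta_folb$contrasts,
         prox_lm = prox_lm, nn_lm = nn_lm)
  })

  manifest <- list(
    package = "vaximg",
    version = as.character(utils::packageVersion("vaximg")),
    schema_version = config$schema_version,
    seed = config$seed, stage_seeds = seeds,
    parameters = config[setdiff(names(config),
                                c("seed", "schema_version"))],
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  result <- list(mri = mri_res, pet = pet_res, radiomics = rad_res,
                 imc = imc_res, stats = stats_res, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(imc_res$ratios,
                     file.path(out_dir, "cell_type_ratios.csv"),
                     row.names = FALSE)
    utils::write.csv(imc_res$spatial,
                     file.path(out_dir, "spatial_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_res$auc, file.path(out_dir, "endpoint_auc.csv"),
                     row.names = FALSE)
    summary <- pipeline_summary(result)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' Flat numeric summary of a pipeline run
#'
#' The headline quantities of one [run_pipeline()] result as a named list
#' of scalars, convenient for manifests and reproducibility checks.
#'
#' @param result a [run_pipeline()] result.
#' @return Named list of numbers.
#' @export
pipeline_summary <- function(result) {
  folb <- result$imc$ratios[
    result$imc$ratios$phenotype == "follicular_B_cell", ]
  list(
    mri_enhancement_volume_mm3 = result$mri$enhancement$volume_mm3,
    mri_lesion_volume_truth_mm3 = result$mri$truth$lesion_volume_mm3,
    mri_lesion_mean_t2_ms = result$mri$lesion_t2_stats$mean,
    pet_enhancement_volume_mm3 = result$pet$enhancement$volume_mm3,
    pet_mean_idg = result$pet$mean_idg,
    pet_total_uptake = result$pet$total_uptake,
    radiomics_pet_energy = result$radiomics$pet_energy,
    radiomics_t2_iqr = result$radiomics$t2_iqr,
    radiomics_m0_dnu = result$radiomics$m0_dnu,
    mean_follicular_b_ratio = mean(folb$ratio),
    mean_fdc_folb_proximity = mean(result$imc$spatial$proximity),
    mean_fdc_folb_nn_um = mean(result$imc$spatial$nn_distance),
    anova_auc_p = result$stats$anova_auc$p_value[1],
    anova_auc_log_diff = result$stats$anova_auc$estimate[1],
    beta_folb_logit_diff = result$stats$beta_folb$estimate[1],
    prox_lm_p = result$stats$prox_lm$p_value[1],
    nn_lm_p = result$stats$nn_lm$p_value[1]
  )
}
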