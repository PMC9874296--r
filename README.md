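# vaximg

Quantification pipeline for preclinical vaccine-reactogenicity imaging
studies that follow local immune activation with serial MRI and ¹⁸FDG
PET/CT and characterise the draining lymph node by imaging mass cytometry
(IMC). The package is aimed at imaging scientists and biostatisticians who
need the complete measurement chain — from raw multi-echo volumes and
per-cell intensity tables to group-level statistics — as tested, scriptable
functions rather than a sequence of vendor tools.

## What it computes

**MRI relaxometry and volumetry.** Per-voxel mono-exponential fits
S(TE) = M0·exp(−TE/T2) over a multi-slice multi-echo acquisition give T2
and M0 parameter maps (ordinary least squares on log-signal, optional
Levenberg–Marquardt refinement). Signal-enhancement volume uses the
contralateral-control rule: threshold = mean + 2·SD of the control-limb
ROI; the enhancement volume is the volume of search-ROI voxels strictly
above it.

**PET quantification.** Measured activity is decay-corrected to injection
time (voxel × 2^(Δt/T½), T½ = 109.77 min for ¹⁸F) and expressed as percent
injected dose per gram, %ID/g = 100·C/D with tissue density 1 g/mL. Total
¹⁸FDG uptake (glycolytic burden) is mean %ID/g in the enhancement mask ×
enhancement volume.

**Radiomics.** First-order energy (Σ x²), first-order interquartile range,
and the gray level dependence matrix Dependence Non-Uniformity,
DNU = Σ_d (Σ_g P(g,d))² / N, with equal-width discretisation over the
in-ROI range, plus correlation-threshold univariate feature selection.

**IMC single-cell pipeline.** Per-channel z-normalisation (population SD),
two-component Gaussian-mixture gating by EM (the higher-mean component is
"positive"; Bayes rule at posterior 0.5), K-means clustering of z-scores
(k-means++ initialisation, multiple restarts), cluster-level phenotype
assignment from canonical-marker rules (e.g. follicular dendritic cells
CD21+CD20−), and per-sample cell-type ratios.

**Spatial metrics.** For phenotypes A and B: the mean number of B cells
within 15 µm of each A cell (boundary inclusive), and the median distance
from each A cell to its nearest B cell, on global 2-D mosaic coordinates.

**Endpoint statistics.** Trapezoidal AUC and group-peak maxima of temporal
endpoint curves; ANOVA on log values with Tukey-adjusted pairwise
contrasts (via emmeans); beta regression of cell-type ratios with logit
link and a 10⁻⁵ pseudo count for zeros (via glmmTMB); square-root / log
transformed linear models for the spatial metrics; Pearson correlation
matrices.

**Synthetic data.** `make_mri_phantom()`, `make_pet_phantom()`,
`make_cell_table()` and `make_endpoint_series()` generate all inputs with
known ground truth (bilateral-limb phantoms with a unilateral lesion,
static PET frames with known dose fractions, lymph-node cell tables with
follicular structure, peaked endpoint curves), so the whole chain is
testable without animal data.

## Worked example

```r
library(vaximg)

# simulate a lymph-node section and run the single-cell pipeline
sim <- make_cell_table(n_cells = 4000, follicle_sd_um = 20,
                       sample_id = "A", seed = 11)
tab <- znormalize(sim$cells)
tab <- gate_cells(tab, seed = 2)
tab <- cluster_cells(tab, k = 15, seed = 3, n_init = 5)
tab <- assign_phenotypes(tab)
mean(tab$phenotype == sim$truth$phenotype)
#> [1] 0.9995
cell_type_ratio(tab)
#>    sample_id                 phenotype n_cells   ratio
#> 1          A   antigen_presenting_cell     497 0.12425
#> 2          A                    B_cell     625 0.15625
#> 3          A          cytotoxic_T_cell     433 0.10825
#> 4          A         follicular_B_cell     991 0.24775
#> 5          A follicular_dendritic_cell     195 0.04875
#> 6          A             helper_T_cell     578 0.14450
#> 7          A                macrophage     323 0.08075
#> 8          A         regulatory_T_cell     181 0.04525
#> 9          A       T_follicular_helper     177 0.04425
#> 10         A                unassigned       0 0.00000
```

99.95% of cells recover their simulated phenotype and the ratios match the
generating composition (25% follicular B cells, 5% FDCs, ...). The full
demonstration pipeline — phantom simulation, T2 mapping, PET
quantification, radiomics, IMC, spatial metrics and statistics — runs from
one configuration:

```r
res <- run_pipeline(default_config(seed = 7))
str(pipeline_summary(res))
#> $ mri_enhancement_volume_mm3 : num 17.3     # T2-map enhancement volume
#> $ mri_lesion_mean_t2_ms      : num 80.1     # true lesion T2 = 80 ms
#> $ pet_total_uptake           : num 6000     # %ID/g x mm^3
#> $ mean_follicular_b_ratio    : num 0.25
#> $ mean_fdc_folb_nn_um        : num 2.47     # FDC -> follicular-B median NN
#> $ anova_auc_p                : num 6.73e-05 # 4x endpoint difference detected
#> ...
```

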