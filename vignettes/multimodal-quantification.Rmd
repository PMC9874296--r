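---
title: "Multimodal quantification of vaccine-induced immune activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal quantification of vaccine-induced immune activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaximg)
```

Intramuscular vaccination triggers a transient local inflammatory response
— reactogenicity — that preclinical studies follow with serial imaging of
the injected hindlimb and its draining (popliteal) lymph node, and with
tissue-level single-cell imaging after necropsy. This vignette describes
the models and procedures the package implements, the parameters that
matter, what the synthetic generators do and do not emulate, and the
numerical decisions taken where the underlying protocols leave choices
open.

## T2 relaxometry

Inflammatory oedema raises the transverse relaxation time T2. A
multi-slice multi-echo (MSME) acquisition samples the decay
$S(\mathrm{TE}) = M_0 e^{-\mathrm{TE}/T_2}$ at each voxel; the default
echo train is eight echoes at TE = 7, 14, …, 56 ms, matching a typical
small-animal protocol (TR long enough that T1 weighting is negligible, so
it is not modelled).

`fit_t2_map()` estimates $T_2$ and $M_0$ per voxel. The default
`log_linear` method is unweighted ordinary least squares of
$\ln S$ on TE — the slope is $-1/T_2$ and the intercept $\ln M_0$.
The `nonlinear` method refines this by Levenberg–Marquardt least squares
on the exponential itself; on noiseless data the two agree to well below
0.5%, and on the data scales used here the log-linear fit is unbiased to
under 2% at 1% noise, so it is the default (the vendor software behind
typical studies does not document its fitting algorithm; unweighted OLS is
the simplest defensible choice).

Degenerate voxels are flagged rather than guessed at:

* any echo at or below `min_signal` → both maps `NA` (log undefined,
  noise-dominated air); such voxels are excluded, never clipped;
* non-decaying signal (slope ≥ 0, e.g. perfectly constant echoes) →
  $T_2 = \infty$ with $M_0$ the geometric-mean signal;
* a volume with no fittable voxel is an error, not an empty map.

## Enhancement volumetry

The enhancement rule mirrors manual contralateral-control analysis: a
control ROI on the uninjected limb gives threshold
$\mu_c + k\,\sigma_c$ (default $k = 2$); the enhancement mask is every
search-ROI voxel *strictly* above it, and the volume is voxel count ×
voxel volume. Two conventions are fixed deliberately:

* $\sigma_c$ is the **population** SD of the control voxels (the
  convention is not documented in typical protocols; with ROIs of hundreds
  of voxels the difference is negligible but must be pinned down for
  reproducibility);
* ties at exactly the threshold are excluded ("exceeding" read strictly);
  adding a constant to both limbs leaves the mask unchanged.

With the threshold at $2\sigma$, about 2.3% of background search voxels
exceed it by chance; accurate volumetry therefore requires the search ROI
to be restricted to the slices showing activation, exactly as a human
analyst restricts the hand-drawn muscle ROI. The acceptance checks use
this slab convention.

## PET quantification

A static frame acquired $\Delta t$ minutes after injection is
decay-corrected to injection time by $2^{\Delta t / T_{1/2}}$
($T_{1/2} = 109.77$ min for ¹⁸F, a physical constant). Concentration is
expressed as $\%\mathrm{ID/g} = 100\,C/D$ with tissue density taken as
1 g/mL so per-mL equals per-g (soft tissue deviates from this by a few
percent; the convention matches standard preclinical reporting). The
injected dose $D$ is the *net* dose — syringe residual already
subtracted by the caller; no syringe model is provided. Total uptake
(glycolytic burden) is the product of mean %ID/g over the enhancement
mask and the mask volume; the product form is implemented as defined,
which for a uniform mask equals the voxel-wise sum of %ID/g × voxel
volume. Decay correction and the %ID/g conversion are both scalar
multiplications and therefore commute.

## Radiomics features

Only the three features that carried signal in the motivating analysis are
implemented, plus the selection rule:

* **first-order energy**: $\sum_i x_i^2$ over in-mask voxels;
* **first-order IQR**: 75th − 25th percentile with linear interpolation
  between order statistics (stated explicitly so the oracle is
  unambiguous);
* **GLDM Dependence Non-Uniformity**: intensities are discretised into
  `n_bins` (default 32) equal-width bins over the in-ROI min–max range —
  this makes the feature invariant under affine intensity rescaling — and
  each voxel's dependence is the number of 26-connected in-ROI neighbours
  whose binned level differs by at most `alpha` (default 0). Neighbours
  outside the ROI are ignored, not counted as non-dependent. With
  $P(g,d)$ the gray-level/dependence histogram,
  $\mathrm{DNU} = \sum_d \big(\sum_g P(g,d)\big)^2 / N$.
  A single-voxel ROI has one voxel with dependence 0, so DNU = 1.

`correlate_features()` computes the Pearson correlation of each feature
with an outcome, drops constant features (undefined $r$) with a message,
and returns features with $|r|$ at or above the threshold ranked by
$|r|$.

## IMC single-cell pipeline

The pipeline consumes a per-cell table (one row per segmented cell with
global mosaic coordinates in µm and per-channel mean intensities);
upstream pixel classification and segmentation are out of scope.

1. **z-normalisation** per channel, population-SD convention, per sample
   by default. Whether normalisation should pool ROIs, samples or the
   whole study is genuinely open; per-sample is the default because
   staining intensity varies between sections, and pooling is a flag.
2. **Gating**: a two-component univariate Gaussian mixture is fitted to
   each channel's z-scores by EM with `n_init` random restarts (best
   log-likelihood kept; restarts guard against local optima). The
   component with the larger mean is the expressing population and a cell
   is positive when its posterior for that component exceeds 0.5 — the
   Bayes rule for the fitted mixture, preferred over a hard intensity cut
   at the component intersection because it uses the component weights.
   Components whose means are separated by less than 0.1 pooled SD are
   flagged as degenerate (unimodal channel; calls unreliable).
3. **Clustering**: K-means on the z-scores with k-means++ seeding,
   `n_init` restarts, best within-cluster sum of squares kept; the
   default $k = 15$ exceeds the nine defined phenotypes, leaving room for
   split populations. The true cluster count in lymph-node tissue is
   unknown; over-clustering is harmless because clusters are mapped to
   phenotypes afterwards.
4. **Phenotype assignment** is rule-based and deterministic (replacing
   the manual inspect-and-label step): a channel is cluster-positive when
   more than half the member cells are gated positive; the cluster takes
   the first definition in priority order whose required-positive markers
   are all cluster-positive and required-negative markers all
   cluster-negative. The default panel orders specific signatures before
   general ones (follicular dendritic cell CD21+CD20−, follicular B
   CD20+Bcl6+, B cell CD20+Bcl6−, Treg CD4+FoxP3+, Tfh CD3+Bcl6+,
   cytotoxic T CD3+CD8+, helper T CD3+CD4+, macrophage CD68+,
   antigen-presenting cell MHCII+). Unmatched clusters are `unassigned`
   and participate in the denominators.
5. **Ratios** are counts over all cells of the sample, aggregating ROIs,
   and sum to 1 including `unassigned`; they are invariant to how a
   sample is split into ROIs.

## Spatial metrics

Both metrics are 2-D centroid-to-centroid on the per-sample mosaic (IMC
sections are 2-D; whether a 15 µm interaction radius should be
centroid-to-centroid or membrane-to-membrane is unstated upstream, and
centroids are what segmentation provides). Proximity is the mean number
of B cells within the radius of each A cell, boundary inclusive ("15 or
less"); nearest-neighbour distance is the median over A cells of the
distance to the closest B cell; self-pairs are excluded when A = B.
Absent phenotypes yield a flagged undefined result, never a silent 0.
Edge effects at section borders are not corrected. The implementation
computes distances from explicit coordinate differences and matches a
naive $O(n^2)$ loop bit-for-bit.

## Endpoint statistics

Per-subject temporal endpoints are summarised two ways: trapezoidal AUC
over the observed timepoints (raw values — no baseline subtraction, a
choice recorded prominently because fold-change AUC ratios depend on it;
missing timepoints are dropped, not imputed) and the group-peak maximum
(every subject read at the timepoint with the highest group mean; ties
resolve to the earliest timepoint, with a message).

Group comparisons mirror the motivating analysis: linear models on
log-transformed summaries with treatment (optionally cohort and their
interaction) as fixed effects, and all pairwise contrasts with Tukey
studentized-range adjustment via emmeans. Non-positive values are an
error instructing the caller to decide an offset policy — silently adding
one would change every fold change. Groups with literally identical
values have no residual variance; their contrast is reported with p = 1.

Cell-type ratios are modelled with a beta likelihood, logit-linked mean
and a single common precision, fitted by maximum likelihood through
glmmTMB; ratios equal to 0 are set to the 10⁻⁵ pseudo count and ratios
equal to 1 to $1 - 10^{-5}$ (the symmetric rule is our extension; only
the zero rule is specified upstream). Spatial proximities use OLS on
square-root transformed outcomes, nearest-neighbour distances OLS on log
outcomes, both with unadjusted pairwise p-values (comparisons
prespecified). Pearson matrices use pairwise-complete observations and
flag undefined correlations (constant columns) as `NA` rather than 0.

## The synthetic generators

The generators define the study conditions for every test:

* **MRI phantom** — two disjoint axis-aligned cylinders ("limbs") with a
  spherical lesion only in the right one; geometry is analytic so volumes
  have closed-form oracles. Defaults: 48×48×12 voxels at
  0.234×0.234×1.5 mm (a 256-matrix, 6 cm field-of-view protocol
  downsampled 5× in-plane to keep test runtimes in seconds), background
  T2 30 ms, lesion T2 80 ms, M0 1000 a.u. Noise is additive Gaussian by
  default — the downstream estimators assume none, and Gaussian keeps the
  oracles closed-form — with Rician magnitude noise as an option (at the
  SNR of these phantoms the Rician bias is negligible).
* **PET phantom** — a single static frame (one 15-min acquisition; no
  time–activity curves) whose truth is a dose-fraction map: 5% of the
  injected dose in the lesion, 1% in a lymph-node spot, 10% spread over
  both limbs; measured activity is the truth scaled by the forward decay
  factor so the correction is testable. 0.66 mm isotropic voxels.
* **Cell table** — each cell gets exactly one true phenotype drawn from a
  realistic lymph-node composition (25% follicular B, 15% B, 15% helper
  T, 12% APC, 10% cytotoxic T, 8% macrophage, 5% each FDC/Tfh/Treg);
  channel intensities come from the positive component for the
  phenotype's signature markers and the negative component otherwise
  (negative mean 1 ± 0.4, positive 6 ± 1 a.u., well separated as after
  spillover compensation). FDCs sit at follicle centers (σ = dispersion/4),
  follicular B cells disperse around them (default σ = 30 µm), all other
  types are uniform over a 1 mm² field.
* **Endpoint curves** — a log-normal-shaped pulse rising from baseline to
  the peak amplitude at the peak time (default 24 h, matching
  inflammation kinetics), multiplied by unit-mean lognormal noise with
  CV 0.2; control treatments are simply low-amplitude pulses. With four
  subjects per group this reproduces the design scale of a typical
  cohort.

What the generators do **not** emulate: anatomy, partial-volume and
scanner artifacts, k-space, B1 inhomogeneity, attenuation/scatter,
cell-segmentation errors, spillover, marker co-expression beyond the
defined signatures, and between-subject correlation of endpoints.
Passing tests therefore demonstrate that the estimators are correct under
their stated models — not that those models capture every property of
in-vivo data.

## Numerical choices and problem sizes

All generators are bit-reproducible from a seed, and the pipeline derives
every stage seed from one top-level seed, so a configuration reproduces
all numeric outputs exactly. EM uses a relative log-likelihood tolerance
of 1e-8 with a 500-iteration cap and a floored component SD; K-means
restarts use Lloyd iterations from k-means++ seeds. Coordinates are
0-based voxel indices with world positions at voxel centers; volumes are
mm³.

The shipped test suite and acceptance script use deliberately modest
sizes — phantoms of ~10⁴–10⁵ voxels, 10,000-cell tables, 100 random
spatial instances up to 2,000 cells, 500 null simulations for ANOVA
calibration — chosen so the full chain re-runs in a few minutes on one
CPU while keeping every statistical check well-powered.

## Known limitations

Single-compartment T2 only; no registration between timepoints (ROIs are
assumed transferable); no SUV or kinetic PET modelling; the radiomics
module is the three named features, not a full IBSI catalogue; phenotype
assignment is hard (cluster-level) rather than probabilistic; spatial
metrics carry no edge correction; and the beta regression uses a single
precision parameter without covariates.
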