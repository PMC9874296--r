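Package: vaximg
Title: Multimodal Quantification of Vaccine-Induced Immune Activation from
    MRI, PET and Imaging Mass Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying local immune activation
    after intramuscular vaccination in preclinical imaging studies.
    Implements multi-echo T2 relaxometry (mono-exponential T2/M0 parameter
    maps), threshold-based signal-enhancement volumetry, decay-corrected PET
    quantification in percent injected dose per gram, a small radiomics
    feature set (first-order energy, interquartile range, and gray level
    dependence matrix dependence non-uniformity), a single-cell imaging mass
    cytometry pipeline (z-normalisation, two-component Gaussian-mixture
    positivity gating, K-means clustering, canonical-marker phenotype
    assignment, cell-type ratios), cell-to-cell spatial proximity and
    nearest-neighbour metrics, and the accompanying endpoint statistics
    (trapezoidal AUC, group-peak maxima, log-scale ANOVA with Tukey
    adjustment, beta regression of compositions, transformed linear models
    and Pearson correlation matrices). A synthetic-data module generates
    phantoms, lymph-node cell tables and temporal endpoint curves with known
    ground truth so that every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    emmeans,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    minpack.lm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
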