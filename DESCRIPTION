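Package: voxelbiome
Title: Voxelwise Mapping of Gut Microbiome-Brain Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Associates a high-dimensional compositional block of gut
    bacterial family relative abundances with many spatial brain targets at
    once. For every voxel of a set of aligned MRI images, a ridge regression
    of the voxel value on the log relative abundances of all bacterial
    families plus covariates (sex, age, BMI) is compared with a
    covariate-only ridge via a 10-fold cross-validated residual-sum-of-squares
    ratio. Inference uses Freedman-Lane permutations with threshold-free
    cluster enhancement (TFCE) for family-wise error control, followed by
    per-family contribution extraction, subgroup sensitivity reruns, and
    FDR-corrected brain-behaviour correlations. Includes a synthetic cohort
    generator with planted ground truth for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
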