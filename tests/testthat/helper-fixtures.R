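# Shared fixtures, generated in code at test time.

# Small planted cohort: quick to simulate, strong signal.
small_planted_cohort <- function(seed = 11, n = 80, noise_sd = 0.5,
                                 image_shape = c(12L, 12L, 12L)) {
  simulate_cohort(planted_scenario(n_subjects = n, noise_sd = noise_sd,
                                   image_shape = image_shape, seed = seed))
}

small_null_cohort <- function(seed = 7, n = 40, image_shape = c(12L, 12L, 12L)) {
  simulate_cohort(null_scenario(n_subjects = n, image_shape = image_shape,
                                seed = seed))
}

# Design + mask + folds bundle for a cohort.
cohort_setup <- function(cohort, K = 10, seed = cohort$scenario$seed) {
  design <- assemble_design(cohort$abundances, cohort$covariates)
  mask <- build_voxel_mask(cohort$stack)
  folds <- make_folds(nrow(design$X), K = K, seed = seed)
  list(design = design, mask = mask, folds = folds)
}

# Tiny inference run restricted to a handful of voxels around the planted
# peak (user-supplied mask), for cheap permutation-based posthoc tests.
tiny_peak_inference <- function(cohort, B = 100, n_extra_voxels = 9) {
  design <- assemble_design(cohort$abundances, cohort$covariates)
  truth_vox <- cohort$truth$signal_voxels
  keep <- c(truth_vox[1], setdiff(cohort$truth$tissue_voxels, truth_vox)[seq_len(n_extra_voxels)])
  m <- array(FALSE, cohort$stack$shape)
  m[keep] <- TRUE
  mask <- build_voxel_mask(cohort$stack, mask = m)
  folds <- make_folds(nrow(design$X), seed = cohort$scenario$seed)
  inf <- run_inference(design, cohort$covariates, cohort$stack, mask, folds,
                       B = B, seed = cohort$scenario$seed)
  list(inf = inf, design = design, mask = mask, folds = folds,
       peak = truth_vox[1])
}
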