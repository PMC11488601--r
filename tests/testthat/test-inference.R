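test_that("Freedman-Lane surrogates preserve the nuisance structure", {
  set.seed(51)
  n <- 60
  Z <- cbind(1, rbinom(n, 1, 0.5), rnorm(n, 45, 10), rnorm(n, 30, 5))
  y <- Z %*% c(2, 0.5, 0.02, 0.1) + rnorm(n)
  # identity permutation returns y itself
  expect_identical(freedman_lane_surrogate(y, Z, seq_len(n)), as.numeric(y))
  # intercept-only nuisance: the surrogate is a plain permutation of y
  p <- sample(n)
  ystar <- freedman_lane_surrogate(y, cbind(rep(1, n)), p)
  expect_equal(ystar, as.numeric(y)[p], tolerance = 1e-12)
  # the mean is preserved for any permutation when Z contains the intercept
  for (b in 1:100) {
    p <- sample(n)
    expect_equal(mean(freedman_lane_surrogate(y, Z, p)), mean(y),
                 tolerance = 1e-10)
  }
  expect_error(freedman_lane_surrogate(y, Z, c(1, 1, 3:n)),
               class = "vb_error_parameter")
})

test_that("permutation p-values count the identity and floor at 1/B", {
  # observed beats all 249 other permutations -> minimum attainable p
  null_list <- c(10, runif(249, 0, 1))
  expect_equal(permutation_pvalues(10, null_list), 1 / 250)
  expect_equal(1 / 250, 0.004)
  # observed at or below every null value -> p = 1
  expect_equal(permutation_pvalues(0, c(0, runif(99))), 1)
  # direct count: null {5,4,3,2,1}, observed 3 -> 3/5
  expect_equal(permutation_pvalues(3, c(5, 4, 3, 2, 1)), 3 / 5)
  expect_error(permutation_pvalues(1, numeric(0)), class = "vb_error_parameter")
})

test_that("FWE correction counts permutation maxima", {
  expect_equal(fwe_correct(2.5, c(10, 3, 2, 1)), 0.5)
  expect_equal(fwe_correct(0, c(10, 3, 2, 1)), 1)
  # monotone nonincreasing in the observed TFCE
  obs <- c(0.5, 1, 2, 5, 11)
  p <- fwe_correct(obs, c(10, 3, 2, 1))
  expect_true(all(diff(p) <= 0))
})

test_that("small cohorts trigger exhaustive permutation enumeration", {
  perms <- voxelbiome:::all_permutations(4)
  expect_length(perms, 24)
  expect_identical(perms[[1]], 1:4)
  expect_equal(length(unique(lapply(perms, paste, collapse = ","))), 24)
  cov <- data.frame(subject_id = letters[1:5], sex = c(0, 1, 0, 1, 0),
                    age = c(30, 40, 50, 35, 45), bmi = c(25, 30, 28, 22, 35))
  sch <- permutation_scheme(cov, matrix(rnorm(10), 5, 2), B = 250, seed = 1)
  expect_true(sch$exhaustive)
  expect_equal(sch$B, 120)
})

test_that("the permutation stream is deterministic and identity-first", {
  p1 <- voxelbiome:::permutation_for(1, 50, 99)
  expect_identical(p1, 1:50)
  p2a <- voxelbiome:::permutation_for(7, 50, 99)
  p2b <- voxelbiome:::permutation_for(7, 50, 99)
  expect_identical(p2a, p2b)
  expect_false(identical(p2a, voxelbiome:::permutation_for(8, 50, 99)))
})

test_that("inference produces coherent p-maps on a planted cohort", {
  co <- small_planted_cohort(seed = 53, n = 60)
  s <- cohort_setup(co)
  inf <- run_inference(s$design, co$covariates, co$stack, s$mask, s$folds,
                       B = 50, seed = 53)
  pu <- inf$p_uncorrected[inf$voxels]
  pf <- inf$p_fwe[inf$voxels]
  expect_true(all(pu >= 1 / inf$B & pu <= 1))
  expect_true(all(pf >= 1 / inf$B & pf <= 1))
  # FWE p dominates the uncorrected p voxelwise
  expect_true(all(pf >= pu - 1e-12))
  # the observed (identity) statistic is the first null column
  expect_equal(inf$stat_null[, 1], inf$ratio[inf$voxels])
  # the truth voxels carry the smallest FWE p
  expect_lte(min(pf), 1 / inf$B + 1e-12)
  expect_true(min(inf$p_fwe[co$truth$signal_voxels]) == min(pf, na.rm = TRUE))
})

test_that("a staged permutation run reproduces the single run bit for bit", {
  co <- small_planted_cohort(seed = 54, n = 40, image_shape = c(10L, 10L, 10L))
  s <- cohort_setup(co)
  inf10 <- run_inference(s$design, co$covariates, co$stack, s$mask, s$folds,
                         B = 10, seed = 54)
  staged <- extend_inference(inf10, 15)
  single <- run_inference(s$design, co$covariates, co$stack, s$mask, s$folds,
                          B = 25, seed = 54)
  expect_identical(staged$stat_null, single$stat_null)
  expect_identical(staged$max_tfce, single$max_tfce)
  expect_identical(staged$p_fwe, single$p_fwe)
  expect_identical(staged$p_uncorrected, single$p_uncorrected)
})

test_that("cluster reporting groups survivors and finds the planted peak", {
  co <- small_planted_cohort(seed = 55, n = 80)
  s <- cohort_setup(co)
  inf <- run_inference(s$design, co$covariates, co$stack, s$mask, s$folds,
                       B = 100, seed = 55)
  cl <- report_clusters(inf)
  expect_gte(nrow(cl), 1)
  expect_true(cl$peak_voxel[1] %in% co$truth$signal_voxels)
  expect_true(all(cl$cs >= 1))
  expect_true(all(cl$p_type %in% c("fwe", "uncorrected")))
  # peak world coordinates agree with the affine
  coord <- c(cl$i[1], cl$j[1], cl$k[1])
  world <- voxelbiome:::voxel_to_world(coord, co$stack$affine)
  expect_equal(c(cl$x[1], cl$y[1], cl$z[1]), as.numeric(world))
  # an all-null inference yields an empty report
  inf_null <- inf
  inf_null$p_fwe[] <- 1
  inf_null$p_uncorrected[] <- 1
  expect_equal(nrow(report_clusters(inf_null)), 0)
})

test_that("connectivity controls how surviving voxels merge into clusters", {
  co <- small_planted_cohort(seed = 56, n = 40, image_shape = c(8L, 8L, 8L))
  s <- cohort_setup(co)
  inf <- run_inference(s$design, co$covariates, co$stack, s$mask, s$folds,
                       B = 10, seed = 56)
  # synthesize a survivor pattern: two diagonal-adjacent voxels
  inf$p_fwe[] <- 1
  inf$p_uncorrected[] <- 1
  inf$ratio[] <- NA
  vox <- s$mask$voxels
  a <- vox[1]
  ac <- voxelbiome:::flat_to_coord(a, inf$shape)
  bc <- ac + c(1, 1, 0)
  b <- voxelbiome:::coord_to_flat(bc, inf$shape)
  inf$p_fwe[c(a, b)] <- 0.01
  inf$ratio[c(a, b)] <- c(2, 1.8)
  cl26 <- report_clusters(inf, connectivity = 26)
  expect_equal(nrow(cl26), 1)
  expect_equal(cl26$cs, 2)
  cl6 <- report_clusters(inf, connectivity = 6)
  expect_equal(nrow(cl6), 2)
  expect_true(all(cl6$cs == 1))
})
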