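test_that("abundance tables are compositional and reproducible", {
  scn <- scenario(n_subjects = 50, n_families = 10, seed = 1)
  ab <- generate_abundances(scn)
  expect_equal(dim(ab$ra), c(50, 10))
  expect_true(all(abs(rowSums(ab$ra) - 1) < 1e-9))
  expect_true(all(ab$ra >= 0))
  ab2 <- generate_abundances(scn)
  expect_identical(ab$ra, ab2$ra)
})

test_that("the requested fraction of families is rare and a collinear pair exists", {
  scn <- scenario(n_subjects = 200, n_families = 10, rare_family_fraction = 0.3,
                  seed = 5)
  ab <- generate_abundances(scn)
  rare_cols <- which(colMeans(ab$ra < 1e-3) > 0.95)
  expect_length(rare_cols, 3)
  # log-scale collinearity between the designated pair
  expect_gt(cor(log(ab$ra[, 1]), log(ab$ra[, 2])), 0.95)
})

test_that("invalid scenarios fail naming the offending field", {
  expect_error(scenario(n_subjects = 10), "n_subjects", class = "vb_error_parameter")
  expect_error(scenario(noise_sd = 0), "noise_sd", class = "vb_error_parameter")
  expect_error(planted_scenario(center = c(50, 5, 5)), "center",
               class = "vb_error_parameter")
  expect_error(planted_scenario(betas = c(Inf, 1)), "betas",
               class = "vb_error_parameter")
})

test_that("covariates have plausible marginals and valid codes", {
  scn <- scenario(n_subjects = 500, seed = 2)
  cov <- generate_covariates(scn)
  expect_true(all(cov$sex %in% c(0, 1)))
  expect_true(all(cov$age >= 22 & cov$age <= 66))
  expect_true(all(cov$bmi >= 19))
  expect_gt(mean(cov$sex), 0.55)  # majority female cohort
})

test_that("null images have the configured noise variance", {
  scn <- null_scenario(n_subjects = 120, noise_sd = 1,
                       covariate_effects = c(sex = 0, age = 0, bmi = 0), seed = 3)
  co <- simulate_cohort(scn)
  v <- apply(co$stack$data[, co$truth$tissue_voxels[1:50]], 2, var)
  # variance of a sample variance at n: 2 sigma^4 / (n - 1)
  tol <- 3 * sqrt(2 / (scn$n_subjects - 1))
  expect_true(all(abs(v - 1) < tol))
})

test_that("in the noiseless limit voxel values equal the linear predictor", {
  scn <- planted_scenario(n_subjects = 25, noise_sd = 1e-9, families = c(3, 5),
                          betas = c(1.5, -1), seed = 4)
  co <- simulate_cohort(scn)
  cl <- co$truth$clusters[[1]]
  gamma <- scn$covariate_effects
  pred <- scn$baseline +
    as.matrix(co$covariates[, c("sex", "age", "bmi")]) %*% gamma +
    log(pmax(co$abundances$ra[, cl$families], 1e-3)) %*% cl$betas
  for (v in cl$voxels) {
    expect_equal(unname(co$stack$data[, v]), as.numeric(pred), tolerance = 1e-6)
  }
})

test_that("the truth record marks exactly the lattice sphere", {
  scn <- planted_scenario(center = c(10, 10, 10), radius = 2,
                          image_shape = c(20L, 20L, 20L), n_subjects = 20,
                          seed = 6)
  co <- simulate_cohort(scn)
  vox <- co$truth$clusters[[1]]$voxels
  # independent enumeration of lattice points within distance 2
  g <- expand.grid(i = 1:20, j = 1:20, k = 1:20)
  d2 <- (g$i - 10)^2 + (g$j - 10)^2 + (g$k - 10)^2
  expected <- which(d2 <= 4)
  expect_identical(vox, expected)
  expect_length(vox, 33)
})

test_that("clinical scores decouple from the brain when the effect is zero", {
  scn <- planted_scenario(n_subjects = 400, clinical_effect = 0,
                          clinical_missing_frac = 0, seed = 8)
  co <- simulate_cohort(scn)
  rm <- rowMeans(co$stack$data[, co$truth$clusters[[1]]$voxels])
  for (v in c("phq9", "stroop_cw")) {
    expect_lt(abs(cor(rm, co$clinical[[v]])), 3 / sqrt(scn$n_subjects))
  }
})

test_that("a strong clinical effect drives the correlation toward 1", {
  scn <- planted_scenario(n_subjects = 300, clinical_effect = 0.99,
                          clinical_missing_frac = 0, seed = 9)
  co <- simulate_cohort(scn)
  rm <- rowMeans(co$stack$data[, co$truth$clusters[[1]]$voxels])
  expect_gt(cor(rm, co$clinical$stroop_cw), 0.9)
})

test_that("the generated correlation matches the requested strength on average", {
  # Monte-Carlo: clinical_effect 0.4, n = 500, 200 replicates; the mean
  # sample correlation should sit within +/- 0.05 of the target.
  base <- planted_scenario(n_subjects = 500, clinical_effect = 0.4,
                           clinical_missing_frac = 0, seed = 100)
  co <- simulate_cohort(base)
  rm <- rowMeans(co$stack$data[, co$truth$clusters[[1]]$voxels])
  rs <- vapply(seq_len(200), function(b) {
    scn_b <- base
    scn_b$seed <- base$seed + b
    clin <- generate_clinical(scn_b, co$stack, co$truth)
    cor(rm, clin$stroop_cw)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.4), 0.05)
})

test_that("clinical generation refuses an effect without a planted region", {
  scn <- null_scenario(n_subjects = 30, seed = 2)
  co <- simulate_cohort(scn)
  scn$clinical_effect <- 0.3
  expect_error(generate_clinical(scn, co$stack, co$truth),
               class = "vb_error_parameter")
})

test_that("the whole cohort is deterministic and aligned", {
  scn <- planted_scenario(n_subjects = 30, seed = 12)
  a <- simulate_cohort(scn)
  b <- simulate_cohort(scn)
  expect_identical(a$abundances$ra, b$abundances$ra)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$abundances$subject_ids, a$covariates$subject_id)
  expect_identical(a$abundances$subject_ids, a$stack$subject_ids)
  expect_error(generate_images(scn, a$abundances, a$covariates[c(2:1, 3:30), ]),
               class = "vb_error_alignment")
})
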