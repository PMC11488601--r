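test_that("family contributions recover a planted positive effect", {
  co <- small_planted_cohort(seed = 61, n = 80)
  tp <- tiny_peak_inference(co, B = 50)
  fc <- family_contributions(tp$inf, tp$design, co$stack, tp$peak)
  planted <- sprintf("family_%03d", co$truth$clusters[[1]]$families)
  top3 <- fc$family[fc$abs_rank <= 3]
  expect_true(all(planted %in% top3))
  expect_true(all(fc$coefficient[fc$family %in% planted] > 0))
  expect_true(all(fc$p_value[fc$family %in% planted] <= 2 / tp$inf$B))
  # stars agree with the p tiers
  expect_true(all((fc$stars == "*") == (fc$p_value < 0.01 & fc$p_value >= 1e-3)))
  # peaks outside the mask are refused
  outside <- setdiff(seq_len(prod(co$stack$shape)), tp$inf$voxels)[1]
  expect_error(family_contributions(tp$inf, tp$design, co$stack, outside),
               class = "vb_error_mask")
})

test_that("the refit coefficient matches an independent normal-equation path", {
  co <- small_planted_cohort(seed = 62, n = 60)
  tp <- tiny_peak_inference(co, B = 10)
  fc <- family_contributions(tp$inf, tp$design, co$stack, tp$peak)
  # independent computation of the partial-ridge refit: project out the
  # nuisance block by explicit least squares, then GCV over the grid via
  # hat-matrix solves on the residualized, scaled family block
  y <- co$stack$data[, tp$peak]
  Z1 <- cbind(1, tp$design$X_raw[, tp$design$covariate_ids])
  Mproj <- diag(length(y)) - Z1 %*% solve(crossprod(Z1), t(Z1))
  Xr <- Mproj %*% tp$design$X_raw[, tp$design$family_ids]
  s <- apply(Xr, 2, sd)
  Xs <- sweep(Xr, 2, s, "/")
  yr <- as.numeric(Mproj %*% y)
  n <- length(y)
  grid <- tp$inf$grid
  best <- NULL; best_gcv <- Inf
  for (lam in grid) {
    A <- crossprod(Xs) + diag(lam, ncol(Xs))
    beta <- solve(A, crossprod(Xs, yr))
    df <- sum(diag(Xs %*% solve(A, t(Xs)))) + ncol(Z1)
    rss <- sum((yr - Xs %*% beta)^2)
    gcv <- if (df < n - 1e-8) n * rss / (n - df)^2 else Inf
    if (gcv <= best_gcv) { best_gcv <- gcv; best <- beta }
  }
  want <- as.numeric(best) / s
  expect_equal(fc$coefficient, unname(want), tolerance = 1e-6)
})

test_that("null-family contribution p-values are approximately uniform", {
  # replicate cohorts; inspect a no-signal family's p at the true peak
  ps <- vapply(1:40, function(b) {
    co <- small_planted_cohort(seed = 700 + b, n = 40,
                               image_shape = c(8L, 8L, 8L))
    tp <- tiny_peak_inference(co, B = 50, n_extra_voxels = 4)
    fc <- family_contributions(tp$inf, tp$design, co$stack, tp$peak)
    fc$p_value[fc$family == "family_020"]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("subgroup reruns are exact for the identity subgroup and guarded", {
  co <- small_planted_cohort(seed = 63, n = 80)
  s <- cohort_setup(co)
  peaks <- co$truth$signal_voxels[1:3]
  all_in <- rep(TRUE, 80)
  res <- subgroup_rerun(all_in, peaks, s$design, co$stack,
                        label = "all", seed = co$scenario$seed)
  expect_true(all(res$delta == 0))
  expect_equal(attr(res, "mean_delta"), 0)
  # the full-sample reference agrees with the statistic map at the peaks
  sm <- rss_ratio_map(s$design, co$stack, s$mask, s$folds)
  expect_equal(res$rss_ratio_full, unname(sm$ratio[peaks]), tolerance = 1e-10)
  # subgroups below 2K subjects are refused
  tiny <- c(rep(TRUE, 5), rep(FALSE, 75))
  expect_error(subgroup_rerun(tiny, peaks, s$design, co$stack),
               class = "vb_error_subgroup_size")
})

test_that("random half subgroups only perturb the peak ratios mildly", {
  # homogeneous cohort with a moderate planted effect (full-sample ratios in
  # the 1.2-1.6 range typical of real findings)
  co <- simulate_cohort(planted_scenario(n_subjects = 80, noise_sd = 1.5,
                                         betas = c(0.7, 0.7), seed = 64))
  s <- cohort_setup(co)
  peak <- co$truth$signal_voxels[1]
  set.seed(640)
  deltas <- vapply(1:50, function(b) {
    sel <- rep(FALSE, 80)
    sel[sample(80, 40)] <- TRUE
    res <- subgroup_rerun(sel, peak, s$design, co$stack,
                          label = "half", seed = 640 + b)
    res$delta
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 0.15)
})

test_that("clinical correlations handle perfect, missing, and constant data", {
  set.seed(65)
  n <- 50
  x <- rnorm(n)
  clin <- data.frame(subject_id = sprintf("S%03d", 1:n),
                     up = x, down = -x, noise = rnorm(n))
  clin$noise[1:5] <- NA
  pv <- cbind(peak_1 = x)
  rep <- clinical_correlations(pv, clin)
  expect_equal(rep$r[rep$variable == "up"], 1, tolerance = 1e-12)
  expect_equal(rep$r[rep$variable == "down"], -1, tolerance = 1e-12)
  expect_equal(rep$n_used[rep$variable == "noise"], 45)
  expect_true(all(rep$q_value >= rep$p_value - 1e-15))
  clin$flat <- rep(2, n)
  expect_warning(rep2 <- clinical_correlations(pv, clin), "constant")
  expect_false("flat" %in% rep2$variable)
})

test_that("FDR flags match a hand-rolled Benjamini-Hochberg step-up", {
  co <- small_planted_cohort(seed = 66, n = 120, noise_sd = 1)
  peaks <- co$truth$signal_voxels[1:2]
  pv <- co$stack$data[, peaks]
  colnames(pv) <- c("peak_a", "peak_b")
  rep <- clinical_correlations(pv, co$clinical)
  manual <- oracle_bh_reject(rep$p_value, 0.05)
  expect_identical(rep$fdr_sig, manual)
  expect_identical(rep$nominal_sig, rep$p_value < 0.05)
  # BH monotonicity: lowering a p-value never removes discoveries
  p2 <- rep$p_value
  p2[which.max(p2)] <- min(p2) / 2
  expect_true(all(oracle_bh_reject(rep$p_value, 0.05) <= oracle_bh_reject(p2, 0.05) |
                    !oracle_bh_reject(rep$p_value, 0.05)))
})
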