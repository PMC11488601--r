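# Permutation inference: Freedman-Lane surrogates, staged permutation budget,
# TFCE-based family-wise error control, and cluster reporting.

# Permutation b of n subjects. b = 1 is always the identity; b > 1 derives its
# own seed from the master seed, so a staged run (50 permutations, then 200
# more) generates exactly the same permutations as a single 250-run.
permutation_for <- function(b, n, seed) {
  if (b == 1) return(seq_len(n))
  set.seed(derive_seed(seed, "perm", b))
  sample(n)
}

# All n! permutations in lexicographic order (identity first), used when n is
# tiny and uniform sampling would duplicate heavily.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- vector("list", factorial(n))
  i <- 0
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in all_permutations(n - 1)) {
      i <- i + 1
      out[[i]] <- c(first, rest[p])
    }
  }
  out
}

#' Build a Freedman-Lane permutation scheme
#'
#' Fits the reduced (covariate-only, ordinary least squares, intercept
#' included) model to every in-mask voxel, keeping fitted values and
#' residuals, and fixes the permutation sequence. The first permutation is
#' always the identity, so the observed statistic is counted in its own null
#' and the minimum attainable p is 1/B. With n <= 7 subjects the n!
#' permutations are enumerated exhaustively instead of sampled.
#'
#' @param covariates data.frame with sex, age, bmi (and subject_id).
#' @param Y subjects x voxels outcome matrix.
#' @param B number of permutations including the identity.
#' @param seed master seed.
#' @return object of class \code{vb_perm_scheme}: \code{fitted},
#'   \code{resid}, \code{B}, \code{seed}, \code{n}, \code{exhaustive}.
#' @export
permutation_scheme <- function(covariates, Y, B = 250, seed = 1L) {
  vb_check(B >= 1, "B must be >= 1", "parameter")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Z <- cbind(intercept = 1, as.matrix(covariates[, c("sex", "age", "bmi")]))
  fit <- qr.fitted(qr(Z), Y)
  resid <- Y - fit
  exhaustive <- n <= 7
  if (exhaustive) {
    perms <- all_permutations(n)
    B <- length(perms)
  } else {
    perms <- NULL
  }
  structure(list(fitted = fit, resid = resid, B = as.integer(B),
                 seed = as.integer(seed), n = n,
                 exhaustive = exhaustive, perms = perms,
                 Z = Z), class = "vb_perm_scheme")
}

scheme_permutation <- function(scheme, b) {
  if (scheme$exhaustive) scheme$perms[[b]] else permutation_for(b, scheme$n, scheme$seed)
}

#' Freedman-Lane surrogate outcome
#'
#' Builds \eqn{y^* = Z\hat\gamma + P_b\,\hat\varepsilon}: the nuisance-only
#' fitted values plus permuted reduced-model residuals. The full statistic
#' pipeline (cross-validation and penalty selection included) is then rerun on
#' \eqn{y^*} with the microbiota block intact, giving an exchangeable null for
#' the microbiota effect in the presence of covariates. The identity
#' permutation returns \code{y} unchanged.
#'
#' @param y outcome vector.
#' @param Z nuisance design including the intercept column.
#' @param perm permutation of subject indices.
#' @param gamma_hat reduced-model coefficients; fitted internally when NULL.
#' @param resid reduced-model residuals \code{y - Z gamma_hat}; fitted
#'   internally when NULL.
#' @return the surrogate outcome vector.
#' @export
freedman_lane_surrogate <- function(y, Z, perm, gamma_hat = NULL, resid = NULL) {
  y <- as.numeric(y)
  vb_check(length(perm) == length(y) && all(sort(perm) == seq_along(y)),
           "perm must be a permutation of the subject indices", "parameter")
  if (identical(as.integer(perm), seq_along(y))) return(y)
  if (is.null(gamma_hat) || is.null(resid)) {
    qz <- qr(Z)
    fitted <- qr.fitted(qz, y)
    resid <- y - fitted
  } else {
    vb_check(length(resid) == length(y), "residual length mismatch", "alignment")
    fitted <- as.numeric(Z %*% gamma_hat)
  }
  as.numeric(fitted + resid[perm])
}

#' Permutation p-values from a null sample
#'
#' \eqn{p = \#\{b : stat_b \ge stat_{obs}\} / B}. The identity permutation's
#' statistic must be element 1 of the null, so the observed value counts in
#' its own null and the minimum attainable p is 1/B (0.004 at B = 250).
#'
#' @param observed numeric vector (one statistic per voxel) or scalar.
#' @param null_stats numeric vector (one voxel) or voxels x B matrix.
#' @return p-values in \code{[1/B, 1]}, same length as \code{observed}.
#' @export
permutation_pvalues <- function(observed, null_stats) {
  if (is.matrix(null_stats)) {
    vb_check(nrow(null_stats) == length(observed),
             "null matrix rows must match observed length", "alignment")
    vb_check(ncol(null_stats) >= 1, "empty null sample", "parameter")
    rowSums(null_stats >= observed) / ncol(null_stats)
  } else {
    vb_check(length(null_stats) >= 1, "empty null sample", "parameter")
    vb_check(length(observed) == 1, "scalar observed expected with vector null",
             "parameter")
    sum(null_stats >= observed) / length(null_stats)
  }
}

#' Family-wise-error-corrected p-values from the max-TFCE null
#'
#' \eqn{p_{FWE}(v) = \#\{b : \max_b \ge TFCE_{obs}(v)\} / B}, where
#' \eqn{\max_b} is the mask-wide maximum TFCE of permutation b (identity
#' included). Monotone nonincreasing in the observed TFCE.
#'
#' @param tfce_observed numeric vector of observed TFCE values.
#' @param max_null numeric vector of per-permutation maxima.
#' @return FWE p-values in [1/B, 1].
#' @export
fwe_correct <- function(tfce_observed, max_null) {
  vb_check(length(max_null) >= 1, "empty permutation null", "parameter")
  vapply(tfce_observed, function(t) mean(max_null >= t), numeric(1))
}

# TFCE of one ratio vector embedded in the mask; returns list(map3d, max).
# The enhanced statistic is max(ratio - 1, 0): the null centres ratios near 1
# and TFCE needs a nonnegative statistic anchored at zero.
ratio_tfce <- function(ratio_vec, voxels, shape, mask_arr, params) {
  s <- array(0, dim = shape)
  s[voxels] <- pmax(ratio_vec - 1, 0)
  enh <- tfce(s, mask_arr, params)
  list(map = enh, max = max(enh))
}

# Process permutations first:last, one surrogate matrix at a time. Every
# permutation runs through the same prepared fold decompositions at the same
# matrix width, so a staged run reproduces a single larger run bit for bit.
process_permutations <- function(first, last, scheme, Y, prep_full, prep_cov,
                                 voxels, shape, mask_arr, params) {
  V <- length(voxels)
  stat_null <- matrix(NA_real_, V, last - first + 1)
  max_tfce <- numeric(last - first + 1)
  tfce_first <- NULL
  for (b in first:last) {
    Yb <- if (b == 1) Y else {
      p <- scheme_permutation(scheme, b)
      scheme$fitted + scheme$resid[p, , drop = FALSE]
    }
    ratio_b <- ratio_guarded(cv_apply(prep_cov, Yb)$rss,
                             cv_apply(prep_full, Yb)$rss)
    tf <- ratio_tfce(ratio_b, voxels, shape, mask_arr, params)
    stat_null[, b - first + 1] <- ratio_b
    max_tfce[b - first + 1] <- tf$max
    if (b == 1) tfce_first <- tf$map
  }
  list(stat_null = stat_null, max_tfce = max_tfce, tfce_observed = tfce_first)
}

#' Permutation inference for the RSS-ratio map
#'
#' Runs Freedman-Lane permutation inference: for each permutation, surrogate
#' outcomes are formed from the covariate-only fit plus permuted residuals and
#' the entire cross-validated RSS-ratio pipeline is rerun (same folds, same
#' penalty grid). Per-voxel uncorrected p-values come from the permutation
#' null of the RSS ratio; family-wise-error-corrected p-values come from the
#' permutation null of the mask-wide maximum TFCE of max(ratio - 1, 0).
#'
#' Use [extend_inference()] to add permutations afterwards; the staged result
#' is identical to a single run with the larger budget.
#'
#' @param design a [assemble_design()] result.
#' @param covariates covariate data.frame (used for the reduced model).
#' @param stack a [image_stack()].
#' @param mask a [build_voxel_mask()] result.
#' @param folds a [make_folds()] assignment shared by all models and
#'   permutations.
#' @param B number of permutations including the identity (default 250).
#' @param seed master seed for the permutation stream; defaults to the fold
#'   seed.
#' @param params a [tfce_params()] object.
#' @param grid ridge penalty grid.
#' @param penalize_covariates see [rss_ratio_map()].
#' @return object of class \code{vb_inference}: 3-D maps \code{ratio},
#'   \code{tfce_observed}, \code{p_uncorrected}, \code{p_fwe}; vectors
#'   \code{max_tfce} (length B) and \code{stat_null} (voxels x B); plus the
#'   scheme and parameter snapshot needed to extend the run.
#' @export
run_inference <- function(design, covariates, stack, mask, folds, B = 250,
                          seed = NULL, params = tfce_params(),
                          grid = lambda_grid(), penalize_covariates = FALSE) {
  vb_check(inherits(mask, "vb_mask"), "mask must be a vb_mask", "parameter")
  check_alignment(design$subject_ids, stack$subject_ids, "design and images")
  seed <- seed %||% folds$seed
  Y <- stack$data[, mask$voxels, drop = FALSE]
  scheme <- permutation_scheme(covariates, Y, B = B, seed = seed)
  B <- scheme$B  # may shrink to n! in the exhaustive case
  preps <- ratio_preps(design, folds, grid, penalize_covariates)
  res <- process_permutations(1L, B, scheme, Y, preps$full, preps$cov,
                              mask$voxels, stack$shape, mask$mask, params)
  finalize_inference(res$stat_null, res$max_tfce, res$tfce_observed,
                     scheme, mask, stack, folds, grid, params, seed,
                     preps$full, preps$cov, penalize_covariates)
}

finalize_inference <- function(stat_null, max_tfce, tfce_observed, scheme,
                               mask, stack, folds, grid, params, seed,
                               prep_full, prep_cov, penalize_covariates) {
  B <- ncol(stat_null)
  ratio_obs <- stat_null[, 1]
  p_unc <- rowSums(stat_null >= ratio_obs) / B
  p_fwe <- fwe_correct(tfce_observed[mask$voxels], max_tfce)
  to_map <- function(v) {
    arr <- array(NA_real_, dim = stack$shape)
    arr[mask$voxels] <- v
    arr
  }
  structure(list(
    ratio = to_map(ratio_obs),
    tfce_observed = tfce_observed,
    p_uncorrected = to_map(p_unc),
    p_fwe = to_map(p_fwe),
    max_tfce = max_tfce,
    stat_null = stat_null,
    B = B, seed = seed, params = params, grid = grid, folds = folds,
    voxels = mask$voxels, shape = stack$shape, affine = stack$affine,
    mask = mask, scheme = scheme,
    prep_full = prep_full, prep_cov = prep_cov,
    penalize_covariates = penalize_covariates
  ), class = "vb_inference")
}

#' Extend a permutation run with additional permutations
#'
#' Mirrors a staged permutation budget: run 50 permutations first, then add
#' 200 more for the promising modalities. Because each permutation's seed
#' derives from the master seed and its absolute index, the extended result is
#' identical to a single run with the full budget.
#'
#' @param inf a [run_inference()] result.
#' @param B_extra number of permutations to add.
#' @return An updated \code{vb_inference} with \code{B + B_extra}
#'   permutations.
#' @export
extend_inference <- function(inf, B_extra) {
  vb_check(inherits(inf, "vb_inference"), "inf must be a vb_inference", "parameter")
  vb_check(B_extra >= 1, "B_extra must be >= 1", "parameter")
  if (inf$scheme$exhaustive) {
    vb_stop("exhaustive enumeration already covers all permutations", "parameter")
  }
  first <- inf$B + 1L
  last <- inf$B + as.integer(B_extra)
  Y <- NULL  # identity (b = 1) never occurs in an extension
  res <- process_permutations(first, last, inf$scheme, Y, inf$prep_full,
                              inf$prep_cov, inf$voxels, inf$shape,
                              inf$mask$mask, inf$params)
  finalize_inference(cbind(inf$stat_null, res$stat_null),
                     c(inf$max_tfce, res$max_tfce),
                     inf$tfce_observed, inf$scheme, inf$mask,
                     list(shape = inf$shape, affine = inf$affine),
                     inf$folds, inf$grid, inf$params, inf$seed,
                     inf$prep_full, inf$prep_cov, inf$penalize_covariates)
}

#' @export
print.vb_inference <- function(x, ...) {
  cat(sprintf("Permutation inference: B = %d, %d voxels; min FWE p = %.4g\n",
              x$B, length(x$voxels), min(x$p_fwe, na.rm = TRUE)))
  invisible(x)
}

#' Report significant clusters
#'
#' Groups surviving voxels into connected clusters and reports one row per
#' cluster with the peak location (the in-cluster voxel with the largest RSS
#' ratio; ties go to the lexicographically smallest voxel index), the ratio at
#' the peak, the cluster size, and the significance regime. Two regimes are
#' evaluated: the primary family-wise-error threshold (FWE p < alpha), and an
#' exploratory regime (uncorrected p at or below the minimum attainable level
#' together with an RSS ratio above \code{ratio_thresh}, i.e. more than a 25\%
#' RSS reduction at the default 1.33).
#'
#' @param inf a [run_inference()] result.
#' @param fwe_alpha FWE threshold (default 0.05, strict).
#' @param p_unc_thresh exploratory uncorrected threshold (default 0.004, the
#'   minimum attainable p at B = 250; inclusive).
#' @param ratio_thresh minimum RSS ratio for exploratory findings.
#' @param connectivity cluster connectivity; default from the TFCE parameters.
#' @return data.frame of class \code{vb_clusters} with columns cluster_id, x,
#'   y, z (world coordinates), i, j, k (voxel), peak_voxel (flat index),
#'   rss_ratio, cs (cluster size), p_type ("fwe"/"uncorrected"), p_value.
#'   Empty when nothing survives.
#' @export
report_clusters <- function(inf, fwe_alpha = 0.05, p_unc_thresh = 0.004,
                            ratio_thresh = 1.33, connectivity = NULL) {
  vb_check(inherits(inf, "vb_inference"), "inf must be a vb_inference", "parameter")
  connectivity <- connectivity %||% inf$params$connectivity
  surv_fwe <- !is.na(inf$p_fwe) & inf$p_fwe < fwe_alpha
  surv_unc <- !is.na(inf$p_uncorrected) & inf$p_uncorrected <= p_unc_thresh &
    inf$ratio > ratio_thresh
  surv <- surv_fwe | surv_unc
  empty <- data.frame(cluster_id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), i = integer(), j = integer(), k = integer(),
                      peak_voxel = integer(), rss_ratio = numeric(),
                      cs = integer(), p_type = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(surv)) return(structure(empty, class = c("vb_clusters", "data.frame")))
  labels <- label_components(surv, connectivity)
  rows <- lapply(seq_len(max(labels)), function(lab) {
    vox <- which(labels == lab)
    ratios <- inf$ratio[vox]
    peak <- vox[which(ratios == max(ratios))[1]]  # which() is in index order
    coord <- flat_to_coord(peak, inf$shape)
    world <- voxel_to_world(coord, inf$affine)
    is_fwe <- any(surv_fwe[vox])
    data.frame(cluster_id = lab,
               x = world[1], y = world[2], z = world[3],
               i = coord[1], j = coord[2], k = coord[3],
               peak_voxel = peak,
               rss_ratio = inf$ratio[peak],
               cs = length(vox),
               p_type = if (is_fwe) "fwe" else "uncorrected",
               p_value = if (is_fwe) inf$p_fwe[peak] else inf$p_uncorrected[peak],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rss_ratio), , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("vb_clusters", "data.frame"))
}
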