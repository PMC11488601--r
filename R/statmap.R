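# The per-voxel association statistic: cross-validated RSS ratio.

ratio_guarded <- function(rss_cov, rss_full) {
  ratio <- rss_cov / rss_full
  zero_full <- rss_full == 0
  if (any(zero_full)) {
    warning(sprintf("%d voxel(s) with zero full-model CV RSS; ratio set to +Inf",
                    sum(zero_full)))
    ratio[zero_full] <- ifelse(rss_cov[zero_full] == 0, 1, Inf)
  }
  ratio
}

# Prepared engines for the two competing models. By default only the
# microbiota block is penalized: the covariates (plus intercept) enter both
# models as an unpenalized nuisance, so the covariate-only model is an
# ordinary least-squares fit and the full model is a partial ridge on the
# covariate-residualized log abundances. With penalize_covariates = TRUE both
# models are classic all-penalized ridges sharing the single penalty grid.
ratio_preps <- function(design, folds, grid = lambda_grid(),
                        penalize_covariates = FALSE, rows = NULL) {
  X_fam <- design$X_raw[, design$family_ids, drop = FALSE]
  X_cov <- design$X_raw[, design$covariate_ids, drop = FALSE]
  if (!is.null(rows)) {
    X_fam <- X_fam[rows, , drop = FALSE]
    X_cov <- X_cov[rows, , drop = FALSE]
  }
  if (penalize_covariates) {
    list(full = cv_prepare(cbind(X_fam, X_cov), folds, grid),
         cov = cv_prepare(X_cov, folds, grid))
  } else {
    empty <- matrix(numeric(0), nrow(X_cov), 0)
    list(full = cv_prepare(X_fam, folds, grid, nuisance = X_cov),
         cov = cv_prepare(empty, folds, grid, nuisance = X_cov))
  }
}

# Compute CV RSS for the covariate-only and full models on a matrix of
# outcome columns, sharing one fold assignment.
rss_ratio_values <- function(design, Y, folds, grid = lambda_grid(),
                             penalize_covariates = FALSE, rows = NULL) {
  preps <- ratio_preps(design, folds, grid, penalize_covariates, rows)
  full <- cv_apply(preps$full, Y)
  cov <- cv_apply(preps$cov, Y)
  list(ratio = ratio_guarded(cov$rss, full$rss), rss_cov = cov$rss,
       rss_full = full$rss, lambda_index_full = full$lambda_index)
}

#' Map the cross-validated RSS-ratio statistic across the brain
#'
#' For every in-mask voxel, fits two ridge regressions of the voxel value --
#' one on the covariates only, one on the covariates plus the log relative
#' abundances of all retained families -- and forms
#' \deqn{RSSratio = RSS_{covariates} / RSS_{microbiota+covariates},}
#' both residual sums of squares computed by 10-fold cross-validation with the
#' SAME fold assignment. Ratios above 1 mean the microbiota improve held-out
#' prediction of that voxel.
#'
#' @param design a [assemble_design()] result.
#' @param stack a [image_stack()] aligned with the design.
#' @param mask a [build_voxel_mask()] result.
#' @param folds a [make_folds()] assignment.
#' @param grid ridge penalty grid shared by both models.
#' @param penalize_covariates if FALSE (default) only the microbiota block is
#'   penalized and the covariates enter both models as an unpenalized
#'   nuisance (the covariate-only model is then an OLS fit); if TRUE both
#'   models are all-penalized ridges.
#' @return object of class \code{vb_statmap}: \code{ratio} (3-D array, NA
#'   outside mask), \code{rss_cov}, \code{rss_full} (per in-mask voxel),
#'   \code{voxels} (flat indices), \code{shape}, \code{affine}.
#' @export
rss_ratio_map <- function(design, stack, mask, folds, grid = lambda_grid(),
                          penalize_covariates = FALSE) {
  vb_check(inherits(design, "vb_design"), "design must be a vb_design", "parameter")
  vb_check(inherits(stack, "vb_image_stack"), "stack must be a vb_image_stack",
           "parameter")
  vb_check(inherits(mask, "vb_mask"), "mask must be a vb_mask", "parameter")
  check_alignment(design$subject_ids, stack$subject_ids, "design and images")
  vb_check(all(mask$shape == stack$shape), "mask and image shapes differ", "alignment")
  Y <- stack$data[, mask$voxels, drop = FALSE]
  vals <- rss_ratio_values(design, Y, folds, grid, penalize_covariates)
  ratio_arr <- array(NA_real_, dim = stack$shape)
  ratio_arr[mask$voxels] <- vals$ratio
  structure(list(ratio = ratio_arr, rss_cov = vals$rss_cov,
                 rss_full = vals$rss_full, voxels = mask$voxels,
                 shape = stack$shape, affine = stack$affine,
                 folds = folds, grid = grid),
            class = "vb_statmap")
}

#' @export
print.vb_statmap <- function(x, ...) {
  r <- x$ratio[x$voxels]
  cat(sprintf("RSS-ratio map: %d voxels; median %.3f, max %.3f\n",
              length(x$voxels), median(r), max(r)))
  invisible(x)
}
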