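# Post-hoc analyses at significant voxels: family contributions, subgroup
# RSS-ratio recomputation, and FDR-corrected brain-behaviour correlations.

# Full-data refit machinery for coefficient extraction. Mirrors the CV
# engine's model: nuisance Z1 = [1 (, covariates)] unpenalized, the family
# block residualized on it, scaled, and penalized; GCV picks the penalty per
# outcome column. Returns family-block coefficients on the log-abundance
# scale (scaling undone).
refit_prepare <- function(design, grid, penalize_covariates = FALSE) {
  if (penalize_covariates) {
    X <- design$X_raw
    Z1 <- cbind(intercept = rep(1, nrow(X)))
    block_cols <- seq_len(ncol(X))
  } else {
    X <- design$X_raw[, design$family_ids, drop = FALSE]
    Z1 <- cbind(intercept = 1,
                design$X_raw[, design$covariate_ids, drop = FALSE])
    block_cols <- seq_along(design$family_ids)
  }
  qz <- qr(Z1)
  cx <- qr.coef(qz, X)
  cx[is.na(cx)] <- 0
  Xr <- X - Z1 %*% cx
  s <- apply(Xr, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  Xr <- sweep(Xr, 2, s, "/")
  sv <- svd(Xr)
  keep <- sv$d > max(sv$d[1], 0) * 1e-12 & sv$d > 0
  fam_rows <- match(design$family_ids, colnames(X))
  list(qz = qz, Z1 = Z1, d = sv$d[keep], U = sv$u[, keep, drop = FALSE],
       V = sv$v[, keep, drop = FALSE], scale = s, grid = grid,
       n = nrow(X), q = ncol(Z1), p = ncol(X), fam_rows = fam_rows)
}

# Coefficients (family rows only, original log-abundance scale) for a batch
# of outcome columns, penalty chosen per column by GCV on the full data.
refit_coefs <- function(prep, Y) {
  Y <- as.matrix(Y)
  gam <- qr.coef(prep$qz, Y)
  gam[is.na(gam)] <- 0
  Yr <- Y - prep$Z1 %*% matrix(gam, ncol = ncol(Y))
  W <- crossprod(prep$U, Yr)
  gcv <- gcv_scores(prep$d, W, colSums(Yr^2), prep$grid, prep$n, df0 = prep$q)
  idx <- pick_lambda(gcv)
  beta <- matrix(0, prep$p, ncol(Y))
  for (li in sort(unique(idx))) {
    cols <- which(idx == li)
    shrink <- prep$d / (prep$d^2 + prep$grid[li])
    beta[, cols] <- prep$V %*% (W[, cols, drop = FALSE] * shrink)
  }
  beta <- beta / prep$scale  # back to the log-abundance scale
  list(beta_family = beta[prep$fam_rows, , drop = FALSE],
       lambda = prep$grid[idx])
}

#' Per-family contributions at significant peaks
#'
#' Refits the full ridge model (penalty by GCV) on the complete sample at
#' each peak voxel and reports each family's signed coefficient on the
#' log-relative-abundance scale (standardization undone). Contribution
#' p-values come from a per-family Freedman-Lane null that reuses the run's
#' permutation set: for family f the reduced model contains the covariates
#' plus all OTHER families, so only f's own association is destroyed in its
#' surrogates. This keeps a no-signal family's null calibrated even at a
#' peak where other families carry real signal (a covariate-only reduced
#' model would let the surviving signal leak into every family's null). No
#' new permutations are drawn. Significance stars: * p < 0.01, ** p < 0.001,
#' *** p < 1e-6 (tiers below 1/B are unreachable at the default budget).
#'
#' @param inf a [run_inference()] result.
#' @param design the [assemble_design()] used for the inference.
#' @param stack the [image_stack()].
#' @param peaks flat voxel indices (e.g. \code{peak_voxel} from
#'   [report_clusters()]).
#' @return data.frame: peak_voxel, family, coefficient, abs_rank, p_value,
#'   stars.
#' @export
family_contributions <- function(inf, design, stack, peaks) {
  vb_check(inherits(inf, "vb_inference"), "inf must be a vb_inference", "parameter")
  vb_check(length(peaks) >= 1, "no peaks given", "parameter")
  vcols <- match(peaks, inf$voxels)
  if (anyNA(vcols)) {
    vb_stop(sprintf("peak voxel(s) outside the analysis mask: %s",
                    paste(peaks[is.na(vcols)], collapse = ", ")), "mask")
  }
  prep <- refit_prepare(design, inf$grid, inf$penalize_covariates)
  fam <- design$family_ids
  n <- inf$scheme$n
  perms <- lapply(seq_len(inf$B), function(b) scheme_permutation(inf$scheme, b))
  X_fam <- design$X_raw[, design$family_ids, drop = FALSE]
  X_cov <- design$X_raw[, design$covariate_ids, drop = FALSE]
  out <- vector("list", length(peaks))
  for (pi in seq_along(peaks)) {
    y <- stack$data[, peaks[pi]]
    obs <- refit_coefs(prep, y)
    coef_raw <- obs$beta_family[, 1]
    pvals <- vapply(seq_along(fam), function(fi) {
      # reduced model for family fi: covariates + all other families
      Zf <- cbind(1, X_cov, X_fam[, -fi, drop = FALSE])
      qf <- qr(Zf)
      fitted_f <- qr.fitted(qf, y)
      resid_f <- y - fitted_f
      Ystar <- vapply(perms, function(p) fitted_f + resid_f[p], numeric(n))
      Ystar[, 1] <- y  # identity permutation: the observed data itself
      cb <- refit_coefs(prep, Ystar)
      absb <- abs(cb$beta_family[fi, ])
      sum(absb >= absb[1]) / inf$B
    }, numeric(1))
    stars <- ifelse(pvals < 1e-6, "***",
                    ifelse(pvals < 1e-3, "**",
                           ifelse(pvals < 0.01, "*", "")))
    out[[pi]] <- data.frame(peak_voxel = peaks[pi], family = fam,
                            coefficient = coef_raw,
                            abs_rank = rank(-abs(coef_raw), ties.method = "first"),
                            p_value = pvals, stars = stars,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recompute RSS ratios at the significant peaks within a subgroup
#'
#' Sensitivity analysis mirroring subgroup recomputation (e.g. overweight
#' only, nonsmokers only, no antidepressants): the RSS ratio is recomputed at
#' the listed peak voxels using only the subgroup's subjects, with freshly
#' assigned folds, and compared to the full-sample ratios. Subgroups smaller
#' than 2K subjects are refused, since K-fold cross-validation is then
#' ill-defined.
#'
#' @param subgroup logical vector, one entry per subject (TRUE = include).
#' @param peaks flat voxel indices of significant peaks.
#' @param design the full-sample [assemble_design()].
#' @param stack the [image_stack()].
#' @param label subgroup label for the report.
#' @param K fold count for the subgroup CV.
#' @param seed the run's master seed: the subgroup fold assignment derives
#'   from it the same way the main run's does, so a subgroup equal to the
#'   whole cohort reproduces the full-sample ratios (and hence zero deltas)
#'   exactly.
#' @param grid ridge penalty grid.
#' @param penalize_covariates see [rss_ratio_map()]; use the main run's
#'   setting.
#' @return data.frame of class \code{vb_subgroup}: label, peak_voxel,
#'   n_subgroup, rss_ratio_subgroup, rss_ratio_full (recomputed at the peaks
#'   on the full sample), delta; mean delta in \code{attr(, "mean_delta")}.
#' @export
subgroup_rerun <- function(subgroup, peaks, design, stack,
                           label = "subgroup", K = 10, seed = 1L,
                           grid = lambda_grid(), penalize_covariates = FALSE) {
  vb_check(is.logical(subgroup) && length(subgroup) == nrow(design$X),
           "subgroup must be a logical vector, one entry per subject", "parameter")
  n_sub <- sum(subgroup)
  if (n_sub < 2 * K) {
    vb_stop(sprintf(
      "subgroup '%s' has too few subjects (%d < %d) for %d-fold cross-validation",
      label, n_sub, 2 * K, K), "subgroup_size")
  }
  idx <- which(subgroup)
  # Full-sample reference ratios, recomputed at the peak voxels only so that
  # subgroup and reference go through numerically identical code paths.
  folds_full <- make_folds(nrow(design$X_raw), K = K, seed = seed)
  ref <- rss_ratio_values(design, stack$data[, peaks, drop = FALSE],
                          folds_full, grid, penalize_covariates)
  folds_sub <- make_folds(n_sub, K = K, seed = seed)
  vals <- rss_ratio_values(design, stack$data[idx, peaks, drop = FALSE],
                           folds_sub, grid, penalize_covariates, rows = idx)
  out <- data.frame(label = label, peak_voxel = peaks, n_subgroup = n_sub,
                    rss_ratio_subgroup = vals$ratio,
                    rss_ratio_full = ref$ratio,
                    delta = vals$ratio - ref$ratio,
                    stringsAsFactors = FALSE)
  attr(out, "mean_delta") <- mean(out$delta)
  class(out) <- c("vb_subgroup", "data.frame")
  out
}

#' Correlate peak brain signals with clinical scores
#'
#' Pearson correlation of each peak's voxel values with each clinical
#' variable on pairwise-complete observations (missing clinical entries are
#' dropped per test, never imputed), with Benjamini-Hochberg FDR correction
#' across all peak-by-variable tests of the run. Two significance tiers are
#' flagged: FDR q < 0.05 and nominal p < 0.05. Constant vectors make the
#' correlation undefined; such pairs are excluded from the FDR family with a
#' warning.
#'
#' @param peak_values subjects x peaks matrix of voxel values (column names
#'   become peak ids), e.g. \code{stack$data[, peaks]}.
#' @param clinical data.frame of clinical scores (subject_id plus numeric
#'   columns).
#' @return data.frame of class \code{vb_correlations}: peak_id, variable, r,
#'   p_value, q_value, n_used, fdr_sig, nominal_sig.
#' @export
clinical_correlations <- function(peak_values, clinical) {
  peak_values <- as.matrix(peak_values)
  vars <- setdiff(names(clinical), "subject_id")
  vb_check(length(vars) >= 1, "clinical table has no score columns", "data")
  peak_ids <- colnames(peak_values) %||% sprintf("peak_%d", seq_len(ncol(peak_values)))
  rows <- list()
  for (pi in seq_len(ncol(peak_values))) {
    for (v in vars) {
      x <- peak_values[, pi]
      y <- clinical[[v]]
      ok <- stats::complete.cases(x, y)
      n_used <- sum(ok)
      if (n_used < 3) {
        vb_stop(sprintf("fewer than 3 complete pairs for %s x %s", peak_ids[pi], v),
                "data")
      }
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        warning(sprintf("constant values for %s x %s; correlation undefined, excluded",
                        peak_ids[pi], v))
        next
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        peak_id = peak_ids[pi], variable = v,
        r = unname(ct$estimate), p_value = ct$p.value, n_used = n_used,
        stringsAsFactors = FALSE)
    }
  }
  vb_check(length(rows) >= 1, "no testable peak x variable pairs", "data")
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$fdr_sig <- out$q_value < 0.05
  out$nominal_sig <- out$p_value < 0.05
  rownames(out) <- NULL
  class(out) <- c("vb_correlations", "data.frame")
  out
}
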