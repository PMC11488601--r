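# Preprocessing: abundance flooring, log transform, prevalence filtering,
# tissue masking, and assembly of the standardized design matrix.

#' Floor tiny relative abundances
#'
#' Replaces every relative abundance below \code{floor} with \code{floor}, so
#' that the subsequent natural-log transform cannot produce outlying values
#' approaching minus infinity. Rows are deliberately NOT renormalized:
#' renormalization would perturb the abundance ratios that the log-scale
#' coefficient patterns encode.
#'
#' @param table a [abundance_table()].
#' @param floor positive floor, default \code{1e-3}.
#' @return The floored table. Columns left constant by flooring are recorded
#'   in \code{attr(, "zero_variance")}.
#' @export
floor_abundances <- function(table, floor = 1e-3) {
  vb_check(inherits(table, "vb_abundance"), "table must be a vb_abundance", "parameter")
  vb_check(is.numeric(floor) && length(floor) == 1 && floor > 0,
           "floor must be a single positive number", "parameter")
  if (any(table$ra < 0)) vb_stop("abundance table contains negative entries", "data")
  ra <- pmax(table$ra, floor)
  out <- abundance_table(ra, table$subject_ids, table$family_ids)
  zv <- table$family_ids[apply(ra, 2, function(x) max(x) - min(x) == 0)]
  attr(out, "zero_variance") <- zv
  attr(out, "floor") <- floor
  out
}

#' Natural-log transform an abundance table
#'
#' Applies the element-wise natural logarithm. The log scale lets a single
#' linear model express abundance-ratio patterns (e.g. coefficients +1/-1 for
#' families A and B encode RA_A/RA_B) and power patterns. Flooring must have
#' been applied first.
#'
#' @param table a [abundance_table()] with strictly positive entries.
#' @return numeric matrix of log abundances.
#' @export
log_transform <- function(table) {
  vb_check(inherits(table, "vb_abundance"), "table must be a vb_abundance", "parameter")
  if (any(table$ra <= 0)) {
    vb_stop("nonpositive abundances: apply floor_abundances() before log_transform()",
            "order_of_operations")
  }
  log(table$ra)
}

#' Prevalence-filter bacterial families
#'
#' Keeps family f iff at least \code{min_subject_frac} of subjects have
#' relative abundance strictly greater than \code{min_ra} (defaults: at least
#' 5\% of subjects above 1\%). The boundary is inclusive on the subject
#' fraction and strict on the abundance. Family order is preserved. Applied to
#' the raw (un-floored) table; flooring only alters values far below
#' \code{min_ra}, so the retained set is unaffected by flooring.
#'
#' @param table a [abundance_table()].
#' @param min_subject_frac minimum fraction of subjects, in (0, 1].
#' @param min_ra abundance that a subject must exceed to count.
#' @return The filtered [abundance_table()].
#' @export
filter_families <- function(table, min_subject_frac = 0.05, min_ra = 0.01) {
  vb_check(inherits(table, "vb_abundance"), "table must be a vb_abundance", "parameter")
  vb_check(min_subject_frac > 0 && min_subject_frac <= 1,
           "min_subject_frac must be in (0, 1]", "parameter")
  frac <- colMeans(table$ra > min_ra)
  keep <- frac >= min_subject_frac
  if (!any(keep)) {
    vb_stop("prevalence filter removed all families (empty design)", "empty_design")
  }
  abundance_table(table$ra[, keep, drop = FALSE], table$subject_ids,
                  table$family_ids[keep])
}

#' Build the voxel inclusion mask
#'
#' Default method: a voxel is analyzed iff its mean intensity across subjects
#' exceeds \code{threshold_frac} times a robust maximum (the 98th percentile
#' of the mean image). This keeps voxels with a moderately large amount of
#' tissue/signal and excludes implausible locations outside the brain.
#' Alternatively a user-supplied mask (array or NIfTI path, nonzero = include)
#' is passed through verbatim.
#'
#' @param stack a [image_stack()].
#' @param mask optional user mask: logical/numeric array or NIfTI path.
#' @param threshold_frac fraction of the robust maximum, default 0.1.
#' @return list of class \code{vb_mask}: \code{mask} (logical 3-D array),
#'   \code{n_voxels}, \code{voxels} (flat indices).
#' @export
build_voxel_mask <- function(stack, mask = NULL, threshold_frac = 0.1) {
  vb_check(inherits(stack, "vb_image_stack"), "stack must be a vb_image_stack", "parameter")
  if (!is.null(mask)) {
    if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
    vb_check(all(dim(mask) == stack$shape), "mask shape differs from images", "alignment")
    m <- array(as.vector(mask) != 0, dim = stack$shape)
  } else {
    mean_img <- colMeans(stack$data)
    thr <- threshold_frac * quantile(mean_img, 0.98, names = FALSE)
    m <- array(mean_img > thr, dim = stack$shape)
  }
  if (!any(m)) {
    vb_stop("voxel mask is empty; lower threshold_frac or supply a mask", "mask")
  }
  structure(list(mask = m, n_voxels = sum(m), voxels = which(m),
                 shape = stack$shape), class = "vb_mask")
}

#' @export
print.vb_mask <- function(x, ...) {
  cat(sprintf("Voxel mask: %d of %d voxels included\n", x$n_voxels, prod(x$shape)))
  invisible(x)
}

#' Assemble the standardized design matrix
#'
#' Applies the preprocessing chain -- prevalence filter, abundance floor,
#' natural log -- to the abundance table, appends the covariates (sex, age,
#' BMI), and standardizes every column to mean 0, sd 1, keeping the per-column
#' means and sds for back-transformation of coefficients. Zero-variance
#' columns are dropped with a warning. Column order is families first, then
#' sex, age, bmi.
#'
#' @param abundances a [abundance_table()] of raw relative abundances.
#' @param covariates data.frame with subject_id, sex, age, bmi.
#' @param floor abundance floor, default 1e-3.
#' @param min_subject_frac,min_ra prevalence-filter parameters.
#' @return An object of class \code{vb_design}: \code{X} (standardized),
#'   \code{X_raw} (log RA + raw covariates), \code{center}, \code{scale},
#'   \code{family_ids}, \code{covariate_ids}, \code{subject_ids}.
#' @export
assemble_design <- function(abundances, covariates, floor = 1e-3,
                            min_subject_frac = 0.05, min_ra = 0.01) {
  vb_check(inherits(abundances, "vb_abundance"), "abundances must be a vb_abundance",
           "parameter")
  check_alignment(abundances$subject_ids, covariates$subject_id,
                  "abundances and covariates")
  filtered <- filter_families(abundances, min_subject_frac, min_ra)
  log_ra <- log_transform(floor_abundances(filtered, floor))
  cov_mat <- as.matrix(covariates[, c("sex", "age", "bmi")])
  X_raw <- cbind(log_ra, cov_mat)
  colnames(X_raw) <- c(filtered$family_ids, "sex", "age", "bmi")

  ctr <- colMeans(X_raw)
  scl <- apply(X_raw, 2, sd)
  zero_var <- scl == 0
  if (any(zero_var)) {
    warning(sprintf("dropping zero-variance design column(s): %s",
                    paste(colnames(X_raw)[zero_var], collapse = ", ")))
    X_raw <- X_raw[, !zero_var, drop = FALSE]
    ctr <- ctr[!zero_var]
    scl <- scl[!zero_var]
  }
  X <- sweep(sweep(X_raw, 2, ctr, "-"), 2, scl, "/")
  structure(list(
    X = X, X_raw = X_raw, center = ctr, scale = scl,
    family_ids = intersect(colnames(X_raw), filtered$family_ids),
    covariate_ids = intersect(colnames(X_raw), c("sex", "age", "bmi")),
    subject_ids = abundances$subject_ids
  ), class = "vb_design")
}

#' Undo design-matrix standardization
#'
#' @param design a \code{vb_design}.
#' @return The unstandardized matrix (log abundances and raw covariates).
#' @export
unstandardize <- function(design) {
  sweep(sweep(design$X, 2, design$scale, "*"), 2, design$center, "+")
}

#' @export
print.vb_design <- function(x, ...) {
  cat(sprintf("Design matrix: %d subjects x (%d families + %d covariates)\n",
              nrow(x$X), length(x$family_ids), length(x$covariate_ids)))
  invisible(x)
}
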