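# Synthetic cohort generator. Emulates the statistical structure the analysis
# assumes -- a compositional family table with a long rare tail and collinear
# families, covariate-correlated images with planted log-abundance signal, and
# clinical scores coupled to the planted regions -- with a known ground truth.

#' Generate a compositional relative-abundance table
#'
#' Families are drawn as log-normal intensities and closed to the simplex, so
#' compositions are heavy-tailed and correlated, the regime ridge regression
#' is designed for. Families 1 and 2 are always generated as a strongly
#' collinear pair (log-scale correlation > 0.95). The last
#' \code{rare_family_fraction} of families receive intensities far below the
#' 1e-3 abundance floor.
#'
#' @param scn a [scenario()].
#' @return A [abundance_table()] whose rows sum to 1 exactly.
#' @export
generate_abundances <- function(scn) {
  vb_check(inherits(scn, "vb_scenario"), "scn must be a vb_scenario", "parameter")
  set.seed(derive_seed(scn$seed, "abundances"))
  n <- scn$n_subjects
  p <- scn$n_families
  n_rare <- round(scn$rare_family_fraction * p)
  n_common <- p - n_rare

  # Geometric-mean abundances decay from ~0.2 to ~0.005 across common families,
  # giving a realistic dominance profile; dispersion 0.7 on the log scale.
  mu <- c(seq(log(0.2), log(0.005), length.out = n_common),
          rep(log(1e-6), n_rare))
  sigma <- c(rep(0.7, n_common), rep(1, n_rare))
  z <- matrix(rnorm(n * p), n, p)
  # Collinear pair: family 2 tracks family 1 up to small log-normal jitter.
  if (n_common >= 2) {
    mu[2] <- mu[1]
    z[, 2] <- z[, 1] + 0.05 * rnorm(n)
  }
  intensity <- exp(sweep(sweep(z, 2, sigma, "*"), 2, mu, "+"))
  ra <- intensity / rowSums(intensity)
  abundance_table(ra, subject_ids = sprintf("S%03d", seq_len(n)))
}

#' Generate a covariate table (sex, age, BMI)
#'
#' Marginals emulate a middle-aged, predominantly female, high-BMI adult
#' cohort: sex ~ Bernoulli(0.69) (1 = female), age ~ Normal(46.7, 10.7)
#' truncated to [22, 66] years, BMI ~ Normal(35.3, 10.9) truncated to
#' [19, 64] kg/m^2.
#'
#' @param scn a [scenario()].
#' @return data.frame with columns subject_id, sex, age, bmi.
#' @export
generate_covariates <- function(scn) {
  vb_check(inherits(scn, "vb_scenario"), "scn must be a vb_scenario", "parameter")
  set.seed(derive_seed(scn$seed, "covariates"))
  n <- scn$n_subjects
  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = rbinom(n, 1, 0.69),
    age = round(rtnorm(n, 46.7, 10.7, 22, 66), 1),
    bmi = round(rtnorm(n, 35.3, 10.9, 19, 64), 1),
    stringsAsFactors = FALSE
  )
}

# Lattice voxels within Euclidean distance `radius` of `center`.
sphere_voxels <- function(center, radius, shape) {
  r <- floor(radius)
  rng <- function(c, d) max(1, c - r):min(d, c + r)
  g <- expand.grid(i = rng(center[1], shape[1]),
                   j = rng(center[2], shape[2]),
                   k = rng(center[3], shape[3]))
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  g <- g[d2 <= radius^2 + 1e-12, , drop = FALSE]
  sort(coord_to_flat(as.matrix(g), shape))
}

tissue_predicate <- function(scn) {
  shape <- scn$image_shape
  ctr <- (shape + 1) / 2
  semi <- scn$tissue_fraction * shape
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]), k = seq_len(shape[3]))
  inside <- ((g$i - ctr[1]) / semi[1])^2 + ((g$j - ctr[2]) / semi[2])^2 +
    ((g$k - ctr[3]) / semi[3])^2 <= 1
  array(inside, dim = shape)
}

#' Generate the image stack and its ground-truth record
#'
#' Inside each planted cluster the subject's voxel value follows
#' \deqn{y = \alpha + \sum_f \beta_f \ln(\max(RA_f, 10^{-3})) + \gamma' cov + \epsilon,}
#' with \eqn{\epsilon \sim N(0, noise\_sd^2)}; outside clusters the abundance
#' effect is zero. All in-tissue voxels carry the baseline intensity plus the
#' covariate effect, so that tissue masking is meaningful; outside the
#' brain-like ellipsoid the intensity is near zero.
#'
#' @param scn a [scenario()].
#' @param abundances output of [generate_abundances()].
#' @param covariates output of [generate_covariates()].
#' @return list with elements \code{stack} (a [image_stack()]) and
#'   \code{truth} (tissue voxels, per-cluster voxel and family indices, affine).
#'   Voxel indices are 1-based column-major flat indices.
#' @export
generate_images <- function(scn, abundances, covariates) {
  vb_check(inherits(scn, "vb_scenario"), "scn must be a vb_scenario", "parameter")
  check_alignment(abundances$subject_ids, covariates$subject_id,
                  "abundances and covariates")
  set.seed(derive_seed(scn$seed, "images"))
  n <- scn$n_subjects
  shape <- scn$image_shape
  V <- prod(shape)
  tissue <- tissue_predicate(scn)
  tissue_idx <- which(tissue)

  cov_mat <- as.matrix(covariates[, c("sex", "age", "bmi")])
  gamma <- scn$covariate_effects[c("sex", "age", "bmi")]
  subj_cov <- as.numeric(cov_mat %*% gamma)

  Y <- matrix(abs(rnorm(n * V, 0, 0.02)), n, V)  # faint out-of-tissue background
  Y[, tissue_idx] <- scn$baseline + subj_cov +
    matrix(rnorm(n * length(tissue_idx), 0, scn$noise_sd), n, length(tissue_idx))

  clusters <- vector("list", length(scn$signal_clusters))
  log_ra <- log(pmax(abundances$ra, 1e-3))
  for (ci in seq_along(scn$signal_clusters)) {
    cl <- scn$signal_clusters[[ci]]
    vox <- sphere_voxels(cl$center, cl$radius, shape)
    signal <- as.numeric(log_ra[, cl$families, drop = FALSE] %*% cl$betas)
    Y[, vox] <- Y[, vox] + signal
    clusters[[ci]] <- list(center = as.integer(cl$center), radius = cl$radius,
                           voxels = vox, families = as.integer(cl$families),
                           betas = as.numeric(cl$betas))
  }

  affine <- default_affine(shape, scn$voxel_size_mm)
  stack <- image_stack(Y, shape = shape, subject_ids = abundances$subject_ids,
                       affine = affine, voxel_size = scn$voxel_size_mm)
  truth <- list(tissue_voxels = tissue_idx,
                clusters = clusters,
                signal_voxels = sort(unique(unlist(lapply(clusters, `[[`, "voxels")))),
                affine = affine, image_shape = shape)
  list(stack = stack, truth = truth)
}

clinical_instruments <- function() {
  # name, mean, sd, min, max, integer-valued
  data.frame(
    variable = c("phq9", "tmt_a", "tmt_b", "stroop_cw", "digit_span"),
    mean = c(6.31, 32.44, 72.78, 43.23, 14.69),
    sd = c(4.39, 12, 40, 10, 4),
    lo = c(0, 5, 0, 0, 0),
    hi = c(27, 200, 300, 100, 30),
    integer = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate clinical scores coupled to the planted brain signal
#'
#' Each score is \code{clinical_effect * standardized(region mean of the first
#' planted cluster) + independent noise} with unit total variance, then mapped
#' onto the instrument's scale (PHQ-9, TMT-A/B, Stroop-CW, Digit Span).
#' With \code{clinical_effect = 0} the scores are independent of the images.
#' A fraction of entries is set missing to exercise pairwise-complete
#' correlation handling.
#'
#' @param scn a [scenario()].
#' @param stack image stack from [generate_images()].
#' @param truth truth record from [generate_images()].
#' @return data.frame with subject_id and one column per instrument.
#' @export
generate_clinical <- function(scn, stack, truth) {
  vb_check(inherits(scn, "vb_scenario"), "scn must be a vb_scenario", "parameter")
  has_signal <- length(truth$clusters) > 0
  if (!has_signal && scn$clinical_effect != 0) {
    vb_stop("clinical_effect != 0 requires at least one planted cluster", "parameter")
  }
  set.seed(derive_seed(scn$seed, "clinical"))
  n <- nrow(stack$data)
  z_region <- if (has_signal) {
    rm <- rowMeans(stack$data[, truth$clusters[[1]]$voxels, drop = FALSE])
    as.numeric(scale(rm))
  } else rep(0, n)
  ce <- scn$clinical_effect
  instruments <- clinical_instruments()
  out <- data.frame(subject_id = stack$subject_ids, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(instruments))) {
    ins <- instruments[r, ]
    latent <- ce * z_region + sqrt(max(0, 1 - ce^2)) * rnorm(n)
    x <- ins$mean + ins$sd * latent
    x <- pmin(pmax(x, ins$lo), ins$hi)
    if (ins$integer) x <- round(x)
    if (scn$clinical_missing_frac > 0) {
      x[runif(n) < scn$clinical_missing_frac] <- NA
    }
    out[[ins$variable]] <- x
  }
  out
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator: covariates, compositional abundance table, image
#' stack with planted signal, and clinical scores. With a fixed scenario seed
#' the whole cohort is bit-reproducible.
#'
#' @param scn a [scenario()].
#' @return An object of class \code{vb_cohort}: list with \code{scenario},
#'   \code{abundances}, \code{covariates}, \code{stack}, \code{clinical},
#'   \code{truth}.
#' @export
simulate_cohort <- function(scn) {
  covariates <- generate_covariates(scn)
  abundances <- generate_abundances(scn)
  img <- generate_images(scn, abundances, covariates)
  clinical <- generate_clinical(scn, img$stack, img$truth)
  structure(list(scenario = scn, abundances = abundances, covariates = covariates,
                 stack = img$stack, clinical = clinical, truth = img$truth),
            class = "vb_cohort")
}

#' @export
print.vb_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d families, %s image, %d planted cluster(s)\n",
              nrow(x$abundances$ra), ncol(x$abundances$ra),
              paste(x$stack$shape, collapse = "x"), length(x$truth$clusters)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes \code{abundances.tsv}, \code{covariates.tsv}, \code{clinical.tsv}
#' (tab-separated, header row, \code{subject_id} first), one NIfTI image per
#' subject under \code{images/}, and \code{truth.json}.
#'
#' @param cohort a \code{vb_cohort}.
#' @param dir output directory (created if needed).
#' @param modality label used in image file names.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, modality = "t2map") {
  vb_check(inherits(cohort, "vb_cohort"), "cohort must be a vb_cohort", "parameter")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  ab <- data.frame(subject_id = cohort$abundances$subject_ids,
                   cohort$abundances$ra, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv <- function(df, f) {
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(ab, "abundances.tsv")
  write_tsv(cohort$covariates, "covariates.tsv")
  write_tsv(cohort$clinical, "clinical.tsv")
  for (i in seq_along(cohort$stack$subject_ids)) {
    f <- file.path(dir, "images", sprintf("%s_%s.nii.gz",
                                          cohort$stack$subject_ids[i], modality))
    write_nifti_image(stack_image(cohort$stack, i), cohort$stack$affine,
                      cohort$stack$voxel_size, f)
  }
  truth <- cohort$truth
  truth$affine <- as.vector(t(truth$affine))  # row-major for JSON readability
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
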