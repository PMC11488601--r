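#' Define a synthetic cohort scenario
#'
#' A scenario fixes every parameter of the synthetic microbiome--brain cohort:
#' cohort size, the compositional family table, image geometry, where signal is
#' planted and how strong it is, covariate effects, and the behavioural
#' coupling. Defaults emulate a mid-size adult cohort (n = 133; predominantly
#' female, middle-aged, high-BMI) with a family-level relative-abundance table
#' carrying a long tail of rare taxa and at least one strongly collinear pair
#' of families.
#'
#' @param n_subjects cohort size (>= 20, so that 10-fold CV is well defined).
#' @param n_families number of bacterial families in the abundance table.
#' @param image_shape integer triple, voxel grid of each image.
#' @param voxel_size_mm positive triple, voxel edge lengths in mm.
#' @param signal_clusters list of clusters; each a list with elements
#'   \code{center} (voxel triple), \code{radius} (in voxels; all voxels within
#'   this Euclidean distance belong to the cluster), \code{families} (indices
#'   of affected families) and \code{betas} (signed effects per log-abundance
#'   unit). \code{list()} gives the global-null scenario.
#' @param covariate_effects named numeric: slope of the voxel value on
#'   \code{sex} (0/1), \code{age} (per year) and \code{bmi} (per kg/m^2),
#'   applied uniformly across tissue.
#' @param noise_sd residual standard deviation of the voxel noise (> 0).
#' @param clinical_effect target correlation between each clinical score and
#'   the standardized mean signal of the first planted cluster.
#' @param rare_family_fraction fraction of families generated almost entirely
#'   below the 1e-3 abundance floor.
#' @param clinical_missing_frac fraction of clinical entries set missing, to
#'   exercise pairwise-complete handling downstream.
#' @param tissue_fraction semi-axes of the "brain" ellipsoid as a fraction of
#'   each image dimension; outside it intensity is near zero.
#' @param baseline mean tissue intensity added to every in-tissue voxel.
#' @param seed integer master seed; the whole cohort is a deterministic
#'   function of the scenario including this seed.
#' @return An object of class \code{vb_scenario}.
#' @seealso [simulate_cohort()]
#' @export
scenario <- function(n_subjects = 133L,
                     n_families = 100L,
                     image_shape = c(12L, 12L, 12L),
                     voxel_size_mm = c(2, 2, 2),
                     signal_clusters = list(),
                     covariate_effects = c(sex = 0.5, age = 0.02, bmi = 0.03),
                     noise_sd = 1,
                     clinical_effect = 0.3,
                     rare_family_fraction = 0.3,
                     clinical_missing_frac = 0.05,
                     tissue_fraction = 0.38,
                     baseline = 10,
                     seed = 1L) {
  chk <- function(ok, field) {
    if (!isTRUE(ok)) vb_stop(sprintf("invalid scenario: field '%s'", field), "parameter")
  }
  chk(is.numeric(n_subjects) && length(n_subjects) == 1 && n_subjects >= 20, "n_subjects")
  chk(is.numeric(n_families) && length(n_families) == 1 && n_families >= 2, "n_families")
  chk(is.numeric(image_shape) && length(image_shape) == 3 && all(image_shape >= 2), "image_shape")
  chk(is.numeric(voxel_size_mm) && length(voxel_size_mm) == 3 && all(voxel_size_mm > 0), "voxel_size_mm")
  chk(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd > 0, "noise_sd")
  chk(is.numeric(clinical_effect) && length(clinical_effect) == 1 &&
        abs(clinical_effect) <= 1, "clinical_effect")
  chk(is.numeric(rare_family_fraction) && rare_family_fraction >= 0 &&
        rare_family_fraction < 1, "rare_family_fraction")
  chk(clinical_missing_frac >= 0 && clinical_missing_frac < 0.5, "clinical_missing_frac")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed")
  chk(is.list(signal_clusters), "signal_clusters")
  for (cl in signal_clusters) {
    chk(all(c("center", "radius", "families", "betas") %in% names(cl)), "signal_clusters")
    chk(length(cl$center) == 3 && all(cl$center >= 1) && all(cl$center <= image_shape),
        "signal_clusters (center outside image)")
    chk(cl$radius >= 0, "signal_clusters (radius)")
    chk(length(cl$families) == length(cl$betas) && all(is.finite(cl$betas)) &&
          all(cl$families >= 1) && all(cl$families <= n_families),
        "signal_clusters (families/betas)")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_families = as.integer(n_families),
    image_shape = as.integer(image_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    signal_clusters = signal_clusters,
    covariate_effects = covariate_effects,
    noise_sd = noise_sd,
    clinical_effect = clinical_effect,
    rare_family_fraction = rare_family_fraction,
    clinical_missing_frac = clinical_missing_frac,
    tissue_fraction = tissue_fraction,
    baseline = baseline,
    seed = as.integer(seed)
  ), class = "vb_scenario")
}

#' Global-null scenario: no microbiota effect anywhere
#'
#' Convenience wrapper for \code{\link{scenario}} with no signal clusters,
#' used for type-I-error calibration.
#'
#' @param clinical_effect defaults to 0 (no planted region exists to couple
#'   the clinical scores to).
#' @param ... passed to [scenario()].
#' @export
null_scenario <- function(clinical_effect = 0, ...) {
  scenario(signal_clusters = list(), clinical_effect = clinical_effect, ...)
}

#' Scenario with one planted spherical signal cluster
#'
#' Plants a sphere of the given radius (radius 2 covers 33 lattice voxels)
#' where the voxel value depends on the log relative abundance of the chosen
#' families.
#'
#' @param center voxel triple; default image centre.
#' @param radius sphere radius in voxels.
#' @param families indices of the contributing families.
#' @param betas signed effect sizes, one per family.
#' @param image_shape passed to [scenario()].
#' @param ... further arguments to [scenario()].
#' @export
planted_scenario <- function(center = NULL, radius = 2, families = c(3L, 4L),
                             betas = c(1, 1), image_shape = c(12L, 12L, 12L), ...) {
  if (is.null(center)) center <- ceiling(image_shape / 2)
  scenario(image_shape = image_shape,
           signal_clusters = list(list(center = center, radius = radius,
                                       families = families, betas = betas)),
           ...)
}

#' @export
print.vb_scenario <- function(x, ...) {
  cat(sprintf("Synthetic cohort scenario: %d subjects, %d families, %s image\n",
              x$n_subjects, x$n_families, paste(x$image_shape, collapse = "x")))
  cat(sprintf("  signal clusters: %d; noise sd: %g; seed: %d\n",
              length(x$signal_clusters), x$noise_sd, x$seed))
  invisible(x)
}
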