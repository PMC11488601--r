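# End-to-end orchestration: configuration, staged execution, provenance.

#' Build a run configuration
#'
#' Gathers every tunable of the pipeline. All randomness descends from the
#' single master \code{seed} (fold assignment, permutation stream, subgroup
#' folds), so identical configurations give identical outputs.
#'
#' @param abundances,covariates,clinical paths to TSV/CSV tables
#'   (\code{clinical} optional).
#' @param images character vector of NIfTI paths or a glob pattern.
#' @param mask optional NIfTI mask path (nonzero = include).
#' @param output_dir run directory for maps, tables and provenance.
#' @param seed master seed (mandatory; no silent nondeterminism).
#' @param floor abundance floor.
#' @param min_subject_frac,min_ra prevalence-filter parameters.
#' @param mask_threshold_frac tissue-mask threshold fraction.
#' @param K cross-validation fold count.
#' @param lambda_n,lambda_range ridge penalty grid (log-spaced).
#' @param B_total,B_stage1 permutation budget; when \code{B_stage1 <
#'   B_total} the run is staged (e.g. 50 then 200 more) and is identical to a
#'   single \code{B_total} run.
#' @param penalize_covariates if FALSE (default) only the microbiota block
#'   carries the ridge penalty (covariates are an unpenalized nuisance); see
#'   [rss_ratio_map()].
#' @param tfce_E,tfce_H,tfce_connectivity,tfce_steps TFCE parameters.
#' @param fwe_alpha,p_uncorrected,rss_ratio_min reporting thresholds.
#' @param subgroups named list of subgroup definitions, each a string
#'   expression over covariate columns (e.g. \code{list(overweight = "bmi > 25")}).
#' @return list of class \code{vb_config}.
#' @export
run_config <- function(abundances = NULL, covariates = NULL, clinical = NULL,
                       images = NULL, mask = NULL, output_dir = "vb_run",
                       seed = NULL, floor = 1e-3, min_subject_frac = 0.05,
                       min_ra = 0.01, mask_threshold_frac = 0.1, K = 10,
                       lambda_n = 20, lambda_range = c(1e-3, 1e3),
                       penalize_covariates = FALSE,
                       B_total = 250, B_stage1 = 50,
                       tfce_E = 0.5, tfce_H = 2, tfce_connectivity = 26,
                       tfce_steps = 100,
                       fwe_alpha = 0.05, p_uncorrected = 0.004,
                       rss_ratio_min = 1.33, subgroups = list()) {
  vb_check(!is.null(seed), "a master seed is mandatory", "parameter")
  vb_check(fwe_alpha > 0 && fwe_alpha <= 1 && p_uncorrected > 0 && p_uncorrected <= 1,
           "thresholds must lie in (0, 1]", "parameter")
  vb_check(B_total >= 1 && B_stage1 >= 1 && B_stage1 <= B_total,
           "need 1 <= B_stage1 <= B_total", "parameter")
  cfg <- list(abundances = abundances, covariates = covariates,
              clinical = clinical, images = images, mask = mask,
              output_dir = output_dir, seed = as.integer(seed), floor = floor,
              min_subject_frac = min_subject_frac, min_ra = min_ra,
              mask_threshold_frac = mask_threshold_frac, K = K,
              lambda_n = lambda_n, lambda_range = lambda_range,
              penalize_covariates = penalize_covariates,
              B_total = B_total, B_stage1 = B_stage1,
              tfce_E = tfce_E, tfce_H = tfce_H,
              tfce_connectivity = tfce_connectivity, tfce_steps = tfce_steps,
              fwe_alpha = fwe_alpha, p_uncorrected = p_uncorrected,
              rss_ratio_min = rss_ratio_min, subgroups = subgroups)
  class(cfg) <- "vb_config"
  cfg
}

#' Load a run configuration from a YAML file
#' @param path YAML file; keys as in [run_config()].
#' @param ... overrides applied on top of the file.
#' @export
load_config <- function(path, ...) {
  vb_check(file.exists(path), sprintf("config file not found: %s", path), "io")
  vals <- yaml::read_yaml(path)
  vals <- modifyList(vals, list(...))
  do.call(run_config, vals)
}

config_snapshot <- function(cfg) {
  cfg[!vapply(cfg, is.null, logical(1))]
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full association pipeline
#'
#' Executes preprocess, association mapping, permutation inference (staged if
#' configured), and post-hoc analyses, writing all maps and tables plus a
#' provenance record to the output directory:
#' \code{mask.nii.gz}, \code{rss_ratio.nii.gz}, \code{tfce.nii.gz},
#' \code{p_uncorrected.nii.gz}, \code{p_fwe.nii.gz}, \code{clusters.tsv},
#' \code{contributions.tsv}, \code{clinical_correlations.tsv},
#' \code{subgroups.tsv}, \code{provenance.json}.
#'
#' @param cfg a [run_config()].
#' @param cohort optional in-memory \code{vb_cohort}; when supplied, the
#'   table/image paths in \code{cfg} are ignored.
#' @return (invisibly) list with the run directory and the main objects:
#'   design, mask, inference, clusters, contributions, correlations,
#'   subgroups.
#' @export
run_pipeline <- function(cfg, cohort = NULL) {
  vb_check(inherits(cfg, "vb_config"), "cfg must be a run_config()", "parameter")
  t0 <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stage_times[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  # --- load -----------------------------------------------------------------
  if (is.null(cohort)) {
    abundances <- read_abundances(cfg$abundances)
    covariates <- read_covariates(cfg$covariates)
    clinical <- if (!is.null(cfg$clinical)) read_clinical(cfg$clinical) else NULL
    paths <- cfg$images
    if (length(paths) == 1 && grepl("[*?]", paths)) paths <- Sys.glob(paths)
    stack <- read_image_stack(sort(paths))
    check_alignment(abundances$subject_ids, stack$subject_ids,
                    "abundances and images")
  } else {
    abundances <- cohort$abundances
    covariates <- cohort$covariates
    clinical <- cohort$clinical
    stack <- cohort$stack
  }
  tick("load")

  # --- preprocess -----------------------------------------------------------
  design <- assemble_design(abundances, covariates, floor = cfg$floor,
                            min_subject_frac = cfg$min_subject_frac,
                            min_ra = cfg$min_ra)
  mask <- build_voxel_mask(stack, mask = cfg$mask,
                           threshold_frac = cfg$mask_threshold_frac)
  message(sprintf("preprocess: %d subjects, %d families retained, %d voxels in mask",
                  nrow(design$X), length(design$family_ids), mask$n_voxels))
  tick("preprocess")

  # --- association + inference ---------------------------------------------
  folds <- make_folds(nrow(design$X), K = cfg$K, seed = cfg$seed)
  grid <- lambda_grid(cfg$lambda_n, cfg$lambda_range)
  params <- tfce_params(E = cfg$tfce_E, H = cfg$tfce_H,
                        connectivity = cfg$tfce_connectivity,
                        n_steps = cfg$tfce_steps)
  inf <- run_inference(design, covariates, stack, mask, folds,
                       B = cfg$B_stage1, seed = cfg$seed, params = params,
                       grid = grid,
                       penalize_covariates = cfg$penalize_covariates)
  if (cfg$B_total > inf$B && !inf$scheme$exhaustive) {
    message(sprintf("inference: extending %d permutations by %d",
                    inf$B, cfg$B_total - inf$B))
    inf <- extend_inference(inf, cfg$B_total - inf$B)
  }
  message(sprintf("inference: B = %d, min FWE p = %.4g", inf$B,
                  min(inf$p_fwe, na.rm = TRUE)))
  tick("inference")

  # --- reporting + posthoc --------------------------------------------------
  clusters <- report_clusters(inf, fwe_alpha = cfg$fwe_alpha,
                              p_unc_thresh = cfg$p_uncorrected,
                              ratio_thresh = cfg$rss_ratio_min)
  contributions <- NULL
  correlations <- NULL
  subgroup_results <- NULL
  if (nrow(clusters) > 0) {
    contributions <- family_contributions(inf, design, stack, clusters$peak_voxel)
    if (!is.null(clinical)) {
      pv <- stack$data[, clusters$peak_voxel, drop = FALSE]
      colnames(pv) <- sprintf("peak_%d", clusters$peak_voxel)
      correlations <- clinical_correlations(pv, clinical)
    }
    if (length(cfg$subgroups) > 0) {
      sub_list <- list()
      for (lab in names(cfg$subgroups)) {
        sel <- eval(parse(text = cfg$subgroups[[lab]]), covariates)
        res <- tryCatch(
          subgroup_rerun(sel, clusters$peak_voxel, design, stack, label = lab,
                         K = cfg$K, seed = cfg$seed, grid = grid,
                         penalize_covariates = cfg$penalize_covariates),
          vb_error_subgroup_size = function(e) {
            message(sprintf("subgroup '%s' skipped: %s", lab, conditionMessage(e)))
            NULL
          })
        if (!is.null(res)) sub_list[[lab]] <- res
      }
      if (length(sub_list)) subgroup_results <- do.call(rbind, sub_list)
    }
  }
  tick("posthoc")

  # --- write ----------------------------------------------------------------
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  write_map_nifti(mask$mask * 1, stack, out("mask.nii.gz"))
  write_map_nifti(inf$ratio, stack, out("rss_ratio.nii.gz"))
  write_map_nifti(inf$tfce_observed, stack, out("tfce.nii.gz"))
  write_map_nifti(inf$p_uncorrected, stack, out("p_uncorrected.nii.gz"))
  write_map_nifti(inf$p_fwe, stack, out("p_fwe.nii.gz"))
  write_tsv_file(format_clusters_tsv(clusters), out("clusters.tsv"))
  if (!is.null(contributions)) write_tsv_file(contributions, out("contributions.tsv"))
  if (!is.null(correlations)) write_tsv_file(correlations, out("clinical_correlations.tsv"))
  if (!is.null(subgroup_results)) write_tsv_file(subgroup_results, out("subgroups.tsv"))
  provenance <- list(
    package = "voxelbiome",
    version = as.character(utils::packageVersion("voxelbiome")),
    r_version = R.version.string,
    config = config_snapshot(cfg),
    n_subjects = nrow(design$X),
    n_families_retained = length(design$family_ids),
    n_voxels = mask$n_voxels,
    B = inf$B,
    stage_seconds = as.list(stage_times),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(provenance, out("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  tick("write")

  invisible(list(dir = cfg$output_dir, design = design, mask = mask,
                 folds = folds, inference = inf, clusters = clusters,
                 contributions = contributions, correlations = correlations,
                 subgroups = subgroup_results))
}

# Stable on-disk representation of the cluster table.
format_clusters_tsv <- function(clusters) {
  df <- as.data.frame(clusters)
  for (col in c("x", "y", "z", "rss_ratio", "p_value")) {
    if (col %in% names(df)) df[[col]] <- formatC(df[[col]], format = "g", digits = 10)
  }
  df
}
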