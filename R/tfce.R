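# Threshold-free cluster enhancement (TFCE) and connected-component labeling.

#' TFCE parameters
#'
#' Defaults follow the de-facto standard parameterization for volumetric
#' data: extent exponent E = 0.5, height exponent H = 2, 26-connectivity,
#' and a step of 1/100 of the map maximum.
#'
#' @param E extent exponent (>= 0).
#' @param H height exponent (>= 0).
#' @param dh integration step; \code{NULL} (default) means max(stat)/100,
#'   recomputed for each map.
#' @param connectivity 6, 18 or 26.
#' @param n_steps number of integration steps when \code{dh} is NULL.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, connectivity = 26,
                        n_steps = 100) {
  vb_check(E >= 0 && H >= 0, "E and H must be nonnegative", "parameter")
  vb_check(is.null(dh) || dh > 0, "dh must be positive", "parameter")
  vb_check(connectivity %in% c(6, 18, 26), "connectivity must be 6, 18 or 26",
           "parameter")
  structure(list(E = E, H = H, dh = dh, connectivity = as.integer(connectivity),
                 n_steps = n_steps), class = "vb_tfce_params")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates cluster extent and height over all supra-threshold levels:
#' \deqn{TFCE(v) = \sum_{h = dh, 2dh, \ldots \le s(v)} e_h(v)^E \, h^H \, dh,}
#' where \eqn{e_h(v)} is the size of the connected component containing
#' \eqn{v} in the supra-threshold set \eqn{\{s \ge h\}}. This gives
#' cluster-like sensitivity without committing to a cluster-forming
#' threshold. The map must be nonnegative on the mask; out-of-mask voxels are
#' ignored.
#'
#' @param stat 3-D numeric array (NA allowed outside the mask).
#' @param mask logical 3-D array or \code{vb_mask}; \code{NULL} uses all
#'   finite voxels.
#' @param params a [tfce_params()] object.
#' @return 3-D array of enhanced values (0 outside the mask).
#' @export
tfce <- function(stat, mask = NULL, params = tfce_params()) {
  vb_check(inherits(params, "vb_tfce_params"), "params must be tfce_params()",
           "parameter")
  dims <- dim(stat)
  vb_check(length(dims) == 3, "stat must be a 3-D array", "parameter")
  s <- as.numeric(stat)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "vb_mask")) mask$mask else mask
    vb_check(all(dim(m) == dims), "mask shape differs from stat", "alignment")
    s[!as.vector(m)] <- 0
  }
  s[!is.finite(s)] <- 0
  mx <- max(s)
  if (mx <= 0) return(array(0, dim = dims))
  dh <- params$dh %||% (mx / params$n_steps)
  out <- .tfce_cpp(s, as.integer(dims), params$E, params$H, dh,
                   params$connectivity)
  array(out, dim = dims)
}

#' Label connected components of a voxel set
#'
#' @param in_set logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return integer 3-D array of component labels (0 outside the set).
#' @export
label_components <- function(in_set, connectivity = 26) {
  dims <- dim(in_set)
  vb_check(length(dims) == 3, "in_set must be a 3-D array", "parameter")
  array(.label_components_cpp(as.logical(in_set), as.integer(dims),
                              as.integer(connectivity)), dim = dims)
}
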