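#' @useDynLib voxelbiome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor.test median p.adjust quantile rbinom rnorm runif sd var
#' @importFrom utils modifyList read.delim write.table
NULL

# Classed conditions so callers (and tests) can dispatch on failure modes.
vb_stop <- function(msg, class) {
  stop(structure(
    list(message = msg, call = sys.call(-1)),
    class = c(paste0("vb_error_", class), "vb_error", "error", "condition")
  ))
}

vb_check <- function(ok, msg, class = "parameter") {
  if (!isTRUE(ok)) vb_stop(msg, class)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from the master seed
#'
#' Every random draw in the pipeline descends from one master seed through
#' this derivation, keyed by a stage tag and an optional index. This is what
#' makes a staged permutation run (50 permutations, then 200 more) bit-identical
#' to a single 250-permutation run: permutation \code{b} always receives the
#' same seed regardless of the batch it is generated in.
#'
#' @param master integer master seed.
#' @param tag character stage tag (e.g. "folds", "perm").
#' @param index optional integer index within the stage.
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(master, tag, index = 0L) {
  vb_check(is.numeric(master) && length(master) == 1 && is.finite(master),
           "master seed must be a single finite number")
  m <- 2147483647  # 2^31 - 1, Mersenne prime; arithmetic kept in doubles
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  s <- (abs(master) %% m)
  s <- (s * 48271) %% m        # Lehmer step decorrelates nearby masters
  s <- (s + h * 7919) %% m
  s <- (s + (index %% m) * 104729) %% m
  as.integer(s)
}

# Flat (column-major) index <-> voxel coordinate helpers.
flat_to_coord <- function(idx, dim) arrayInd(idx, .dim = dim)
coord_to_flat <- function(coord, dim) {
  coord <- rbind(coord)
  as.integer((coord[, 3] - 1) * dim[1] * dim[2] + (coord[, 2] - 1) * dim[1] + coord[, 1])
}

# world = affine %*% (voxel - 1, 1); matches the NIfTI sform convention used
# when images are written to disk.
voxel_to_world <- function(coord, affine) {
  coord <- rbind(coord)
  t(affine %*% rbind(t(coord) - 1, 1))[, 1:3, drop = FALSE]
}

# Default affine: scaled identity with the volume centre at world origin.
default_affine <- function(shape, voxel_size) {
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_size
  aff[1:3, 4] <- -voxel_size * (shape - 1) / 2
  aff
}
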