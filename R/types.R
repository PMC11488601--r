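# Core data containers. Light S3: plain lists with validators, in the style of
# base-R statistical packages; heavy numerics live in matrices throughout.

#' Construct an abundance table
#'
#' Subjects x bacterial-families relative abundances. Values must lie in
#' [0, 1]; each row is a composition (sums to ~1 for raw tables, but tables
#' that have been floored are no longer renormalized and may sum to slightly
#' more than 1).
#'
#' @param ra numeric matrix, subjects in rows, families in columns.
#' @param subject_ids,family_ids character vectors; defaults taken from
#'   dimnames.
#' @return An object of class \code{vb_abundance}.
#' @export
abundance_table <- function(ra, subject_ids = rownames(ra), family_ids = colnames(ra)) {
  ra <- as.matrix(ra)
  vb_check(is.numeric(ra), "abundance matrix must be numeric", "data")
  if (anyNA(ra)) vb_stop("abundance table contains missing values", "data")
  if (any(ra < 0)) vb_stop("abundance table contains negative entries", "data")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(ra)))
  if (is.null(family_ids)) family_ids <- sprintf("family_%03d", seq_len(ncol(ra)))
  dimnames(ra) <- list(subject_ids, family_ids)
  structure(list(ra = ra, subject_ids = subject_ids, family_ids = family_ids),
            class = "vb_abundance")
}

#' @export
print.vb_abundance <- function(x, ...) {
  cat(sprintf("Relative-abundance table: %d subjects x %d families\n",
              nrow(x$ra), ncol(x$ra)))
  invisible(x)
}

#' Construct an image stack
#'
#' One spatially aligned 3-D image per subject, stored internally as a
#' subjects x voxels matrix (column-major voxel order) for fast voxelwise
#' regression.
#'
#' @param data subjects x voxels numeric matrix, or a list of 3-D arrays.
#' @param shape integer triple (required when \code{data} is a matrix).
#' @param subject_ids character vector of subject identifiers.
#' @param affine 4x4 voxel-to-world matrix (1-based voxel convention, see
#'   [voxel_to_world()]); default scaled identity centred on the volume.
#' @param voxel_size voxel edge lengths in mm (used for the default affine).
#' @export
image_stack <- function(data, shape = NULL, subject_ids = NULL,
                        affine = NULL, voxel_size = c(2, 2, 2)) {
  if (is.list(data) && !is.matrix(data)) {
    shapes <- unique(lapply(data, dim))
    vb_check(length(shapes) == 1 && length(shapes[[1]]) == 3,
             "all images must share one 3-D shape", "alignment")
    shape <- shapes[[1]]
    data <- do.call(rbind, lapply(data, as.vector))
  }
  vb_check(is.matrix(data) && is.numeric(data), "image data must be a numeric matrix", "data")
  vb_check(!is.null(shape) && length(shape) == 3 && prod(shape) == ncol(data),
           "shape must be a 3-D triple matching the voxel count", "parameter")
  if (is.null(subject_ids)) subject_ids <- rownames(data) %||% sprintf("S%03d", seq_len(nrow(data)))
  if (is.null(affine)) affine <- default_affine(shape, voxel_size)
  rownames(data) <- subject_ids
  structure(list(data = data, shape = as.integer(shape), subject_ids = subject_ids,
                 affine = affine, voxel_size = as.numeric(voxel_size)),
            class = "vb_image_stack")
}

#' Extract one subject's image as a 3-D array
#' @param stack a \code{vb_image_stack}.
#' @param subject subject id or row index.
#' @export
stack_image <- function(stack, subject) {
  i <- if (is.character(subject)) match(subject, stack$subject_ids) else subject
  vb_check(!is.na(i) && i >= 1 && i <= nrow(stack$data), "unknown subject", "parameter")
  array(stack$data[i, ], dim = stack$shape)
}

#' @export
print.vb_image_stack <- function(x, ...) {
  cat(sprintf("Image stack: %d subjects, %s voxels (%.3g MB)\n",
              nrow(x$data), paste(x$shape, collapse = "x"),
              utils::object.size(x$data) / 2^20))
  invisible(x)
}

check_alignment <- function(ids_a, ids_b, what = "tables") {
  if (length(ids_a) != length(ids_b) || !all(ids_a == ids_b)) {
    missing_a <- setdiff(ids_b, ids_a)
    missing_b <- setdiff(ids_a, ids_b)
    detail <- if (length(missing_a) || length(missing_b)) {
      sprintf(" (missing: %s)", paste(c(missing_a, missing_b), collapse = ", "))
    } else " (same ids, different order)"
    vb_stop(sprintf("subject ids of %s do not match%s", what, detail), "alignment")
  }
  invisible(TRUE)
}
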