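# Disk I/O: TSV tables and NIfTI-1 images (via RNifti).

read_table_checked <- function(path, what) {
  if (!file.exists(path)) {
    vb_stop(sprintf("%s file not found: %s", what, path), "io")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vb_check("subject_id" %in% names(df),
           sprintf("%s table must have a subject_id column", what), "data")
  df
}

#' Read a relative-abundance table from TSV/CSV
#'
#' Expects a header row and a \code{subject_id} first column; remaining
#' columns are family relative abundances in [0, 1]. Missing values are an
#' error.
#'
#' @param path file path.
#' @return A [abundance_table()].
#' @export
read_abundances <- function(path) {
  df <- read_table_checked(path, "abundance")
  ra <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  storage.mode(ra) <- "double"
  abundance_table(ra, subject_ids = as.character(df$subject_id))
}

#' Read a covariate table (subject_id, sex, age, bmi) from TSV/CSV
#' @param path file path.
#' @export
read_covariates <- function(path) {
  df <- read_table_checked(path, "covariate")
  need <- c("sex", "age", "bmi")
  vb_check(all(need %in% names(df)),
           "covariate table must have columns sex, age, bmi", "data")
  if (anyNA(df[, need])) vb_stop("covariate table contains missing values", "data")
  vb_check(all(df$sex %in% c(0, 1)), "sex must be coded 0/1", "data")
  vb_check(all(df$age > 0) && all(df$bmi > 0), "age and BMI must be positive", "data")
  df[, c("subject_id", need)]
}

#' Read a clinical-score table from TSV/CSV
#' @param path file path.
#' @export
read_clinical <- function(path) {
  read_table_checked(path, "clinical")
}

#' Read spatially aligned NIfTI images into an image stack
#'
#' @param paths character vector of NIfTI file paths, one per subject.
#' @param subject_ids subject identifiers; default derived from file names.
#' @return A [image_stack()]. All images must share shape and affine (within
#'   1e-4).
#' @export
read_image_stack <- function(paths, subject_ids = NULL) {
  vb_check(length(paths) >= 1, "no image paths given", "io")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    vb_stop(paste("image file(s) not found:", paste(missing, collapse = ", ")), "io")
  }
  if (is.null(subject_ids)) {
    subject_ids <- sub("(_[^_]*)?\\.nii(\\.gz)?$", "", basename(paths))
  }
  imgs <- lapply(paths, RNifti::readNifti)
  shapes <- unique(lapply(imgs, dim))
  vb_check(length(shapes) == 1 && length(shapes[[1]]) == 3,
           "images differ in shape or are not 3-D", "alignment")
  affs <- lapply(imgs, function(im) {
    a <- unclass(RNifti::xform(im))
    attributes(a) <- list(dim = dim(a))
    a
  })
  for (a in affs[-1]) {
    vb_check(max(abs(a - affs[[1]])) < 1e-4, "images differ in affine", "alignment")
  }
  vsz <- abs(diag(affs[[1]])[1:3])
  data <- do.call(rbind, lapply(imgs, as.vector))
  image_stack(data, shape = shapes[[1]], subject_ids = subject_ids,
              affine = affs[[1]], voxel_size = vsz)
}

write_nifti_image <- function(arr, affine, voxel_size, path) {
  im <- RNifti::asNifti(array(as.numeric(arr), dim = dim(arr)))
  RNifti::pixdim(im) <- voxel_size
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Write a 3-D map as NIfTI (float32)
#'
#' @param map 3-D numeric array (NA allowed outside the mask).
#' @param stack the [image_stack()] supplying affine and voxel size.
#' @param path output file (.nii or .nii.gz).
#' @export
write_map_nifti <- function(map, stack, path) {
  arr <- array(as.numeric(map), dim = stack$shape)
  arr[is.na(arr)] <- 0
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- stack$voxel_size
  im <- RNifti::`sform<-`(im, structure(stack$affine, code = 2L))
  RNifti::writeNifti(im, path, datatype = "float")
  invisible(path)
}
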