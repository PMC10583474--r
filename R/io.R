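# NIfTI-1 volume IO and JSON model serialisation. Volumes round-trip voxel
# values bit-exactly and spacing to 1e-6 mm; orientation is normalised to
# RAS+ on read.

#' Write a volume or mask grid as NIfTI-1
#'
#' @param x an [image_volume], or a 3-D integer/logical array (masks) plus
#'   `spacing`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing spacing override, required when `x` is a bare array.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "image_volume")) {
    arr <- x$voxels
    spacing <- x$spacing
  } else {
    arr <- x
    if (is.null(spacing)) stop_domain("spacing required for bare arrays")
    if (is.logical(arr)) { arr <- array(as.integer(arr), dim(arr)) }
  }
  if (length(dim(arr)) != 3L) stop_domain("only 3-D volumes are written")
  if (!dir.exists(dirname(path))) stop_domain("parent directory does not exist: %s", dirname(path))
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @return An [image_volume]; orientation is normalised to RAS+.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  im <- tryCatch(RNifti::readNifti(path),
                 error = function(e) stop_domain("malformed NIfTI: %s", conditionMessage(e)))
  if (length(dim(im)) != 3L)
    stop_domain("expected a 3-D image, got %d dimension(s)", length(dim(im)))
  if (!identical(RNifti::orientation(im), "RAS")) RNifti::orientation(im) <- "RAS"
  image_volume(array(as.numeric(im), dim(im)), RNifti::pixdim(im))
}

#' Write a phantom case to a directory as NIfTI + truth masks
#'
#' One file per (timepoint, kind): `<id>_<pre|post>_<image|observed|truth>.nii.gz`.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- case$meta$case_id
  for (tp in c("pre", "post")) {
    side <- case[[tp]]
    if (!is.null(side$image))
      write_volume(side$image, file.path(dir, sprintf("%s_%s_image.nii.gz", id, tp)))
    write_volume(side$seg$observed, file.path(dir, sprintf("%s_%s_observed.nii.gz", id, tp)),
                 spacing = side$seg$spacing)
    if (!is.null(side$seg$truth))
      write_volume(side$seg$truth, file.path(dir, sprintf("%s_%s_truth.nii.gz", id, tp)),
                   spacing = side$seg$spacing)
  }
  invisible(dir)
}

#' Serialise a trained logistic model as JSON
#'
#' @param model a `logistic_model`.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  payload <- list(intercept = model$intercept,
                  coefficients = as.list(model$coefficients),
                  threshold = model$threshold,
                  l2_strength = model$l2_strength,
                  patch_size = model$patch_size,
                  bin_width = model$bin_width,
                  standardization = list(mean = as.list(model$standardization$mean),
                                         sd = as.list(model$standardization$sd),
                                         kept = model$standardization$kept),
                  catalogue_version = model$catalogue_version,
                  seed = model$seed, n_iter = model$n_iter)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a logistic model from JSON
#'
#' @param path JSON file written by [write_model_json()].
#' @return A `logistic_model`.
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = p$intercept,
                 coefficients = unlist(p$coefficients),
                 threshold = p$threshold, l2_strength = p$l2_strength,
                 patch_size = p$patch_size, bin_width = p$bin_width,
                 standardization = list(mean = unlist(p$standardization$mean),
                                        sd = unlist(p$standardization$sd),
                                        kept = p$standardization$kept),
                 catalogue_version = p$catalogue_version,
                 seed = p$seed, n_iter = p$n_iter, converged = TRUE),
            class = "logistic_model")
}
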