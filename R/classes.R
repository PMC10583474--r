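#' Label codes used in observed segmentation masks
#'
#' Observed labels: 0 background, 1 liver outside the future liver remnant
#' (FLR), 2 FLR parenchyma, 3 vessel, 4 tumour. Truth labels (phantoms only,
#' defined where observed == 2): 0 not applicable, 1 functional parenchyma,
#' 2 oedema/congestion.
#'
#' @format A named integer vector.
#' @export
SEG_LABELS <- c(background = 0L, liver = 1L, flr = 2L, vessel = 3L, tumour = 4L)

#' @rdname SEG_LABELS
#' @export
TRUTH_LABELS <- c(na = 0L, functional = 1L, oedema = 2L)

#' Construct a 3-D image volume
#'
#' The unit every analysis stage operates on: a 3-D grid of CT-like intensity
#' (Hounsfield-unit scale) with physical voxel spacing.
#'
#' @param voxels numeric 3-D array of intensities; all finite.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm offset of the first voxel.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_domain("voxels must be a 3-D array")
  if (any(dim(voxels) < 8L))
    stop_domain("grid dimensions must be >= 8 per axis")
  if (!all(is.finite(voxels)))
    stop_domain("all intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_domain("spacing must be 3 positive finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm; HU range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct an aligned segmentation mask set
#'
#' @param observed integer 3-D array with labels as in [SEG_LABELS].
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param truth optional integer 3-D array with labels as in [TRUTH_LABELS];
#'   must be non-zero only where `observed == 2`.
#' @return An object of class `seg_mask_set`.
#' @export
seg_mask_set <- function(observed, spacing, truth = NULL) {
  if (!is.array(observed) || length(dim(observed)) != 3L)
    stop_domain("observed must be a 3-D array")
  if (!all(observed %in% SEG_LABELS))
    stop_domain("observed labels must be in {0,1,2,3,4}")
  storage.mode(observed) <- "integer"
  if (!is.null(truth)) {
    if (!identical(dim(truth), dim(observed)))
      stop_domain("truth grid shape must match observed")
    if (!all(truth %in% TRUTH_LABELS))
      stop_domain("truth labels must be in {0,1,2}")
    if (any(truth != 0L & observed != SEG_LABELS[["flr"]]))
      stop_domain("truth may be non-zero only where observed == 2 (FLR parenchyma)")
    storage.mode(truth) <- "integer"
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_domain("spacing must be 3 positive values (mm)")
  structure(list(observed = observed, truth = truth, spacing = spacing),
            class = "seg_mask_set")
}

#' @export
print.seg_mask_set <- function(x, ...) {
  tab <- table(factor(x$observed, levels = SEG_LABELS, labels = names(SEG_LABELS)))
  cat(sprintf("<seg_mask_set> %s voxels; %s; truth: %s\n",
              paste(dim(x$observed), collapse = "x"),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
              if (is.null(x$truth)) "absent" else "present"))
  invisible(x)
}

#' Construct per-case patient metadata
#'
#' @param case_id character identifier.
#' @param height_cm height in cm, within `[120, 220]`.
#' @param weight_kg weight in kg, within `[30, 200]`.
#' @param technique `"ALPPS"` or `"PVE"`.
#' @param days_elapsed integer days between hepatic modulation and the
#'   post-modulation imaging study; >= 1.
#' @param phlf_grade post-hepatectomy liver failure grade: `"none"`, `"A"`,
#'   `"B"` or `"C"` (ISGLS).
#' @return An object of class `patient_meta`.
#' @export
patient_meta <- function(case_id, height_cm, weight_kg, technique,
                         days_elapsed, phlf_grade = "none") {
  technique <- match.arg(technique, c("ALPPS", "PVE"))
  phlf_grade <- match.arg(phlf_grade, c("none", "A", "B", "C"))
  if (height_cm < 120 || height_cm > 220) stop_domain("height_cm outside [120, 220]")
  if (weight_kg < 30 || weight_kg > 200) stop_domain("weight_kg outside [30, 200]")
  if (!is_count(days_elapsed) || days_elapsed < 1) stop_domain("days_elapsed must be an integer >= 1")
  structure(list(case_id = as.character(case_id), height_cm = height_cm,
                 weight_kg = weight_kg, technique = technique,
                 days_elapsed = as.integer(days_elapsed), phlf_grade = phlf_grade),
            class = "patient_meta")
}

# voxel volume in cc for a spacing vector in mm
voxel_cc <- function(spacing) prod(spacing) / 1000
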