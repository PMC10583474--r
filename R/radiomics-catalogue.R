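# The frozen 106-feature catalogue: 19 first-order + 16 shape + 22 GLCM +
# 16 GLRLM + 16 GLSZM + 12 GLDM + 5 NGTDM, in canonical order. The ordered
# name list also ships as inst/extdata/catalogue.json.

CATALOGUE_VERSION <- "1.0"

#' Canonical ordered names of the 106-feature catalogue
#'
#' @return Character vector of length 106.
#' @export
catalogue_names <- function() {
  c(FO_NAMES, SHAPE_NAMES, GLCM_NAMES, GLRLM_NAMES, GLSZM_NAMES, GLDM_NAMES,
    NGTDM_NAMES)
}

#' Analysable FLR parenchyma mask
#'
#' The future-liver-remnant parenchyma with the vascular and tumour regions
#' removed from the analysis (optionally with a safety margin dilated around
#' them).
#'
#' @param seg a [seg_mask_set].
#' @param dilate_margin margin in voxels by which vessel/tumour exclusions are
#'   grown (default 0).
#' @param case_id,timepoint provenance strings carried on the result.
#' @return Object of class `analysis_mask`: list with logical `mask`,
#'   `spacing`, `n_voxels` and provenance fields.
#' @export
flr_analysis_mask <- function(seg, dilate_margin = 0, case_id = NA_character_,
                              timepoint = NA_character_) {
  stopifnot(inherits(seg, "seg_mask_set"))
  if (!any(seg$observed == SEG_LABELS[["flr"]]))
    stop_domain("no analysable FLR parenchyma: FLR label absent")
  excl <- seg$observed == SEG_LABELS[["vessel"]] | seg$observed == SEG_LABELS[["tumour"]]
  if (dilate_margin > 0 && any(excl)) {
    d <- chamfer_dist_cpp(as.logical(excl), dim(excl))
    excl <- d / 3 <= dilate_margin
  }
  mask <- seg$observed == SEG_LABELS[["flr"]] & !excl
  if (!any(mask)) stop_domain("no analysable FLR parenchyma")
  structure(list(mask = mask, spacing = seg$spacing, n_voxels = sum(mask),
                 case_id = case_id, timepoint = timepoint),
            class = "analysis_mask")
}

#' Extract the full 106-feature vector for a region
#'
#' First-order (19) + shape (16) + texture (71) in canonical order; bit-for-bit
#' repeatable on identical input.
#'
#' @param volume an [image_volume].
#' @param analysis_mask an [flr_analysis_mask()] result, or a logical 3-D
#'   array.
#' @param config list; `bin_width` (default 25 HU, fixed-width bins anchored
#'   at the region minimum).
#' @return Named numeric vector of length 106 with attributes `case_id`,
#'   `timepoint` and `catalogue_version`.
#' @export
extract_catalogue <- function(volume, analysis_mask, config = list(bin_width = 25)) {
  stopifnot(inherits(volume, "image_volume"))
  if (inherits(analysis_mask, "analysis_mask")) {
    mask <- analysis_mask$mask
    prov <- c(analysis_mask$case_id, analysis_mask$timepoint)
  } else {
    mask <- analysis_mask
    prov <- c(NA_character_, NA_character_)
  }
  bw <- config$bin_width %||% 25
  vals <- volume$voxels[mask]
  fo <- first_order_features(vals, bin_width = bw,
                             voxel_volume_mm3 = prod(volume$spacing))
  sh <- shape_features(mask, volume$spacing)
  tx <- texture_features(volume, mask, bin_width = bw)
  out <- c(fo, sh, tx)
  stopifnot(identical(names(out), catalogue_names()))
  attr(out, "case_id") <- prov[1]
  attr(out, "timepoint") <- prov[2]
  attr(out, "catalogue_version") <- CATALOGUE_VERSION
  out
}

#' Standardise a feature matrix
#'
#' Columns are z-scored with mean and standard deviation estimated on
#' `fit_rows` only (the training split); columns that are constant on the
#' fitting rows (sd < 1e-12) are dropped with a warning and recorded in the
#' returned parameters.
#'
#' @param matrix numeric matrix (rows = observations, named columns).
#' @param fit_rows integer row indices to estimate parameters on (default all
#'   rows); at least 2.
#' @return List with `z` (standardised matrix, dropped columns removed) and
#'   `params` (list `mean`, `sd`, `kept`, `dropped`).
#' @export
standardize <- function(matrix, fit_rows = seq_len(nrow(matrix))) {
  if (length(fit_rows) < 2) stop_domain("need at least 2 fitting rows")
  m <- colMeans(matrix[fit_rows, , drop = FALSE])
  s <- apply(matrix[fit_rows, , drop = FALSE], 2, sd)
  dropped <- colnames(matrix)[s < 1e-12]
  kept <- setdiff(colnames(matrix), dropped)
  if (length(kept) == 0) stop_domain("all columns constant on the fitting rows")
  if (length(dropped))
    warning(sprintf("dropping %d constant column(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")))
  params <- list(mean = m[kept], sd = s[kept], kept = kept, dropped = dropped)
  list(z = apply_standardization(matrix, params), params = params)
}

#' Apply stored standardisation parameters to new rows
#'
#' @param matrix numeric matrix containing at least the kept columns.
#' @param params `params` element of a [standardize()] result.
#' @export
apply_standardization <- function(matrix, params) {
  z <- sweep(matrix[, params$kept, drop = FALSE], 2, params$mean)
  sweep(z, 2, params$sd, "/")
}
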