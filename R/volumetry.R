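# Liver remnant volumetry. Volumes in cc, percentages on the 0-100+ scale,
# BSA in m^2. TLV and TV are measured on the pre-modulation study and the
# normaliser (TLV - TV) is held fixed across timepoints so pre and post
# percentages are comparable.

#' Volume of a labelled region in cc
#'
#' @param mask_grid integer 3-D array of labels.
#' @param label label value to count.
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @return Volume in cc: `count * prod(spacing) / 1000`.
#' @export
mask_volume_cc <- function(mask_grid, label, spacing_mm) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop_domain("spacing must be positive")
  sum(mask_grid == label) * voxel_cc(spacing_mm)
}

#' Anatomic future liver remnant volume percentage
#'
#' `FRLV% = FRL / (TLV - TV) x 100`.
#'
#' @param frl_cc anatomic future liver remnant, cc.
#' @param tlv_cc total liver volume (pre-modulation), cc.
#' @param tv_cc tumour volume (pre-modulation), cc.
#' @return Percentage (may exceed 100).
#' @export
frlv_pct <- function(frl_cc, tlv_cc, tv_cc) {
  den <- tlv_cc - tv_cc
  if (any(den <= 0)) stop_domain("TLV - TV must be positive")
  frl_cc / den * 100
}

#' Functional future liver remnant volume percentage
#'
#' `FRFxV% = FRFx / (TLV - TV) x 100`; always <= [frlv_pct()] when
#' `frfx_cc <= frl_cc`.
#'
#' @param frfx_cc functional future liver remnant, cc.
#' @inheritParams frlv_pct
#' @export
frfxv_pct <- function(frfx_cc, tlv_cc, tv_cc) {
  frlv_pct(frfx_cc, tlv_cc, tv_cc)
}

#' Relative pre-to-post volumetric increase
#'
#' `iFRL% = (FRLpost - FRLpre) / FRLpre x 100` (identically for iFRFx%). May
#' be negative when the remnant shrinks.
#'
#' @param post_cc,pre_cc volumes in cc; `pre_cc > 0`.
#' @export
growth_pct <- function(post_cc, pre_cc) {
  if (any(pre_cc <= 0)) stop_domain("pre volume must be positive")
  (post_cc - pre_cc) / pre_cc * 100
}

#' Body surface area (Mosteller)
#'
#' `BSA = sqrt(height(cm) x weight(kg) / 3600)`, m^2.
#'
#' @param height_cm,weight_kg positive.
#' @export
bsa_m2 <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop_domain("height and weight must be positive")
  sqrt(height_cm * weight_kg / 3600)
}

#' BSA-standardised future liver remnant percentage
#'
#' The FLR divided by the BSA-estimated standardised total liver volume
#' `-794.41 + 1267.28 x BSA`, times 100. Requires
#' `BSA > 794.41 / 1267.28 ~ 0.62686` m^2 for a positive denominator.
#'
#' @param frl_cc future liver remnant, cc.
#' @param bsa body surface area, m^2.
#' @export
sflr_pct <- function(frl_cc, bsa) {
  den <- -794.41 + 1267.28 * bsa
  if (any(den <= 0))
    stop_domain("standardised TLV non-positive: BSA must exceed %.5f m^2", 794.41 / 1267.28)
  frl_cc / den * 100
}

#' Kinetic growth rate
#'
#' Remnant growth in percentage points per day between modulation and
#' reassessment: `(FRLV%post - FRLV%pre) / days`.
#'
#' @param frlv_post_pct,frlv_pre_pct remnant volume percentages.
#' @param days_elapsed days between modulation and post imaging; >= 1.
#' @export
kgr_pct_per_day <- function(frlv_post_pct, frlv_pre_pct, days_elapsed) {
  if (any(days_elapsed < 1)) stop_domain("days_elapsed must be >= 1")
  (frlv_post_pct - frlv_pre_pct) / days_elapsed
}

#' Full volumetry record for one case
#'
#' Populates every volumetric parameter from a phantom case's masks plus a
#' functional-volume (FRFx) pair, which may come either from the phantom truth
#' masks or from the texture classifier ([estimate_frfx()]).
#'
#' @param case a `phantom_case`.
#' @param frfx_pre_cc,frfx_post_cc functional remnant volumes, cc. Defaults to
#'   the case's truth values.
#' @param kgr_basis growth-rate basis: `"frlv"` (percentage points of FRLV per
#'   day, default) or `"sflr"` (points of sFLR per day).
#' @return One-row data.frame (class `volumetry_record`) with columns
#'   `tlv_cc, tv_cc, frl_pre_cc, frl_post_cc, frfx_pre_cc, frfx_post_cc,
#'   frlv_pre_pct, frfxv_pre_pct, frlv_pct, frfxv_pct, ifrl_pct, ifrfx_pct,
#'   bsa_m2, sflr_pct, kgr_pct_per_day`.
#' @export
compute_volumetry <- function(case,
                              frfx_pre_cc = NULL, frfx_post_cc = NULL,
                              kgr_basis = c("frlv", "sflr")) {
  kgr_basis <- match.arg(kgr_basis)
  stopifnot(inherits(case, "phantom_case"))
  sp <- case$pre$seg$spacing
  tlv <- case$tlv_cc
  tv <- case$tv_cc
  frl_pre <- mask_volume_cc(case$pre$seg$observed, SEG_LABELS[["flr"]], sp)
  frl_post <- mask_volume_cc(case$post$seg$observed, SEG_LABELS[["flr"]], sp)
  if (is.null(frfx_pre_cc))
    frfx_pre_cc <- mask_volume_cc(case$pre$seg$truth, TRUTH_LABELS[["functional"]], sp)
  if (is.null(frfx_post_cc))
    frfx_post_cc <- mask_volume_cc(case$post$seg$truth, TRUTH_LABELS[["functional"]], sp)
  bsa <- bsa_m2(case$meta$height_cm, case$meta$weight_kg)
  frlv_pre <- frlv_pct(frl_pre, tlv, tv)
  frlv_post <- frlv_pct(frl_post, tlv, tv)
  kgr <- if (kgr_basis == "frlv") {
    kgr_pct_per_day(frlv_post, frlv_pre, case$meta$days_elapsed)
  } else {
    kgr_pct_per_day(sflr_pct(frl_post, bsa), sflr_pct(frl_pre, bsa), case$meta$days_elapsed)
  }
  rec <- data.frame(
    case_id = case$meta$case_id, technique = case$meta$technique,
    phlf_grade = case$meta$phlf_grade,
    tlv_cc = tlv, tv_cc = tv,
    frl_pre_cc = frl_pre, frl_post_cc = frl_post,
    frfx_pre_cc = frfx_pre_cc, frfx_post_cc = frfx_post_cc,
    frlv_pre_pct = frlv_pre, frfxv_pre_pct = frfxv_pct(frfx_pre_cc, tlv, tv),
    frlv_pct = frlv_post, frfxv_pct = frfxv_pct(frfx_post_cc, tlv, tv),
    ifrl_pct = growth_pct(frl_post, frl_pre),
    ifrfx_pct = growth_pct(frfx_post_cc, frfx_pre_cc),
    bsa_m2 = bsa, sflr_pct = sflr_pct(frl_post, bsa),
    kgr_pct_per_day = kgr,
    stringsAsFactors = FALSE)
  class(rec) <- c("volumetry_record", class(rec))
  rec
}

#' Write volumetry records to CSV
#'
#' @param records data.frame of stacked [compute_volumetry()] rows.
#' @param path output file.
#' @export
write_volumetry_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
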