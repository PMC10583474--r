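# Primary outcome: how well each volumetric predictor separates severe
# post-hepatectomy liver failure (PHLF >= B). Secondary outcome: anatomic vs
# functional growth contrasted between ALPPS and PVE. Raw Mann-Whitney
# p-values are reported without multiple-testing correction.

PRIMARY_PREDICTORS <- c("frfxv_pct", "frlv_pct", "sflr_pct", "kgr_pct_per_day")
PRIMARY_ROWS <- c("frl_post_cc", "frfx_post_cc", "frlv_pct", "frfxv_pct",
                  "ifrl_pct", "ifrfx_pct", "sflr_pct", "kgr_pct_per_day")
SECONDARY_ROWS <- c("tlv_cc", "frl_pre_cc", "frfx_pre_cc", "frlv_pre_pct",
                    "frfxv_pre_pct", "frl_post_cc", "frfx_post_cc",
                    "frlv_pct", "frfxv_pct", "ifrl_pct", "ifrfx_pct")

#' Is a PHLF grade clinically severe (>= B)?
#'
#' @param grade character vector of grades in `c("none", "A", "B", "C")`.
#' @export
phlf_severe <- function(grade) grade %in% c("B", "C")

group_summary_row <- function(values, groups) {
  g1 <- values[groups]; g2 <- values[!groups]
  mw <- if (length(g1) >= 1 && length(g2) >= 1) mann_whitney_u(g1, g2)$p else NA_real_
  c(median_1 = median(g1), lo_1 = suppressWarnings(min(g1)), hi_1 = suppressWarnings(max(g1)),
    median_2 = median(g2), lo_2 = suppressWarnings(min(g2)), hi_2 = suppressWarnings(max(g2)),
    p = mw)
}

#' Primary outcome analysis: predictors of severe PHLF
#'
#' Computes, over a cohort of volumetry records, the ROC AUC of FRFxV, FRLV,
#' sFLR and KGR for predicting PHLF >= B (volume predictors are scored
#' lower-is-positive: smaller functional remnants mean higher failure risk)
#' together with per-group medians/ranges and Mann-Whitney p per row.
#'
#' @param records data.frame of stacked [compute_volumetry()] rows, including
#'   a `phlf_grade` column.
#' @return List with `auc` (data.frame predictor/auc), `table` (per-variable
#'   group summaries), `n_severe`, `n_mild`. Degenerate outcome groups
#'   (< 2 cases) yield NA statistics with a warning rather than an error.
#' @export
primary_outcome <- function(records) {
  severe <- phlf_severe(records$phlf_grade)
  n_severe <- sum(severe); n_mild <- sum(!severe)
  degenerate <- n_severe < 2 || n_mild < 2
  if (degenerate)
    warning("fewer than 2 cases in an outcome group; statistics reported as NA")
  auc <- data.frame(predictor = PRIMARY_PREDICTORS,
                    auc = vapply(PRIMARY_PREDICTORS, function(v) {
                      if (degenerate) return(NA_real_)
                      roc_auc(records[[v]], severe, direction = "lower")$auc
                    }, numeric(1)),
                    direction = "lower-is-positive",
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- t(vapply(PRIMARY_ROWS, function(v)
    group_summary_row(records[[v]], !severe), numeric(7)))
  tab <- data.frame(variable = PRIMARY_ROWS,
                    median_mild = tab[, 1], lo_mild = tab[, 2], hi_mild = tab[, 3],
                    median_severe = tab[, 4], lo_severe = tab[, 5], hi_severe = tab[, 6],
                    p = if (degenerate) NA_real_ else tab[, 7],
                    stringsAsFactors = FALSE, row.names = NULL)
  list(auc = auc, table = tab, n_severe = n_severe, n_mild = n_mild)
}

#' Secondary outcome analysis: ALPPS vs PVE volumetric contrast
#'
#' Medians and ranges of the baseline and post-modulation volumetric
#' parameters per technique, with a Mann-Whitney p for each contrast.
#'
#' @param records data.frame of stacked [compute_volumetry()] rows with a
#'   `technique` column containing both techniques.
#' @return data.frame with one row per volumetric parameter.
#' @export
secondary_outcome <- function(records) {
  is_alpps <- records$technique == "ALPPS"
  if (!any(is_alpps) || all(is_alpps))
    stop_domain("both techniques must be present")
  tab <- t(vapply(SECONDARY_ROWS, function(v)
    group_summary_row(records[[v]], is_alpps), numeric(7)))
  data.frame(variable = SECONDARY_ROWS,
             median_alpps = tab[, 1], lo_alpps = tab[, 2], hi_alpps = tab[, 3],
             median_pve = tab[, 4], lo_pve = tab[, 5], hi_pve = tab[, 6],
             p = tab[, 7], stringsAsFactors = FALSE, row.names = NULL)
}

fmt_row <- function(label, med, lo, hi) sprintf("%s %.2f (%.2f-%.2f)", label, med, lo, hi)

#' Render the outcome tables as a Markdown report
#'
#' @param primary result of [primary_outcome()].
#' @param secondary result of [secondary_outcome()].
#' @param path output file.
#' @export
render_outcome_report <- function(primary, secondary, path) {
  lines <- c("# Cohort outcome report", "",
             sprintf("Severe PHLF (>= B): %d of %d cases", primary$n_severe,
                     primary$n_severe + primary$n_mild), "",
             "## Predictors of PHLF >= B (lower-is-positive AUC)", "",
             "| predictor | AUC |", "|---|---|",
             sprintf("| %s | %.3f |", primary$auc$predictor, primary$auc$auc), "",
             "## Post values by PHLF group (median (range), Mann-Whitney p)", "",
             "| variable | PHLF < B | PHLF >= B | p |", "|---|---|---|---|",
             sprintf("| %s | %.2f (%.2f-%.2f) | %.2f (%.2f-%.2f) | %.3f |",
                     primary$table$variable,
                     primary$table$median_mild, primary$table$lo_mild, primary$table$hi_mild,
                     primary$table$median_severe, primary$table$lo_severe,
                     primary$table$hi_severe, primary$table$p), "",
             "## ALPPS vs PVE (median (range), Mann-Whitney p)", "",
             "| variable | ALPPS | PVE | p |", "|---|---|---|---|",
             sprintf("| %s | %.2f (%.2f-%.2f) | %.2f (%.2f-%.2f) | %.3f |",
                     secondary$variable,
                     secondary$median_alpps, secondary$lo_alpps, secondary$hi_alpps,
                     secondary$median_pve, secondary$lo_pve, secondary$hi_pve,
                     secondary$p), "",
             "Raw p-values; no multiple-testing correction is applied.")
  writeLines(lines, path)
  invisible(path)
}
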