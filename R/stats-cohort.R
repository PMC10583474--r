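# Cohort-level statistics: Mann-Whitney U with exact enumeration at small n,
# chi-square, Spearman, Shapiro-Wilk screening and ROC/AUC with the mid-rank
# tie convention that makes AUC = U / (n1 * n2) an identity.

#' Mann-Whitney U test
#'
#' U for `x` with mid-rank ties. The two-sided p-value is exact by
#' enumeration of all label assignments when `n1 + n2 <= 12` (ties included),
#' and a tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y non-empty numeric vectors.
#' @return List with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_domain("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(ix, r) sum(r[ix]) - length(ix) * (length(ix) + 1) / 2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- u_stat(seq_len(n1), r)
  if (n1 + n2 <= 12) {
    combos <- combn(n1 + n2, n1)
    us <- apply(combos, 2, u_stat, r = r)
    p <- min(1, 2 * min(mean(us <= U), mean(us >= U)))
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    s2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    mu <- n1 * n2 / 2
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(s2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(U = U, p = p, method = method)
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; `df = (r - 1)(c - 1)`.
#'
#' @param contingency_table matrix of non-negative counts, at least 2x2.
#' @return List with `stat`, `df`, `p`.
#' @export
chi_square <- function(contingency_table) {
  tab <- as.matrix(contingency_table)
  if (any(dim(tab) < 2)) stop_domain("table must be at least 2x2")
  if (any(tab < 0)) stop_domain("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_domain("zero marginal in contingency table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(stat = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks.
#'
#' @param x,y equal-length vectors of length >= 3.
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_domain("x and y must have equal length >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_domain("Spearman correlation undefined for a constant vector")
  cor(x, y, method = "spearman")
}

#' Shapiro-Wilk normality screen
#'
#' Reported in outputs as a screening statistic only; nothing is gated on it.
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return List with `W`, `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000) stop_domain("n must be in [3, 5000]")
  if (length(unique(x)) < 2) stop_domain("constant input")
  sw <- shapiro.test(x)
  list(W = unname(sw$statistic), p = unname(sw$p.value))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores with ties contributing one half, so
#' the AUC equals the Mann-Whitney U equivalent `U_pos / (n_pos * n_neg)` and
#' the trapezoidal integral of the curve.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcome (TRUE/1 = positive); both classes present.
#' @param direction `"higher"` if larger scores indicate the positive class,
#'   `"lower"` otherwise.
#' @return Object of class `roc_curve`: list with `thresholds`, `fpr`, `tpr`,
#'   `auc`, `n_pos`, `n_neg`, `direction`.
#' @export
roc_auc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop_domain("both classes must be present")
  s <- if (direction == "lower") -scores else scores
  n_pos <- sum(y); n_neg <- sum(!y)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(s[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!y] >= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg, direction = direction),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (%d pos / %d neg, %s-is-positive)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}
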