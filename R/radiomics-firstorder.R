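# First-order (histogram / intensity) features. The grouped implementation
# computes all 19 features for many regions (patches) at once with
# order-statistic indexing; the single-region wrapper is the same code with
# one group.

FO_NAMES <- c("fo_energy", "fo_total_energy", "fo_entropy", "fo_minimum",
              "fo_p10", "fo_p90", "fo_maximum", "fo_mean", "fo_median",
              "fo_iqr", "fo_range", "fo_mad", "fo_rmad", "fo_rms", "fo_sd",
              "fo_variance", "fo_skewness", "fo_kurtosis", "fo_uniformity")

#' Discretise intensities with a fixed bin width
#'
#' Fixed-bin-width convention: `bin(v) = floor((v - anchor) / bin_width) + 1`
#' with the anchor at the region minimum by default.
#'
#' @param values numeric vector, non-empty.
#' @param bin_width positive bin width (HU).
#' @param anchor left edge of bin 1; defaults to `min(values)`.
#' @return List with `bins` (1-based indices), `histogram` (counts summing to
#'   `length(values)`) and `n_levels`.
#' @export
discretize <- function(values, bin_width, anchor = min(values)) {
  if (length(values) == 0) stop_domain("cannot discretise an empty region")
  if (bin_width <= 0) stop_domain("bin_width must be positive")
  bins <- floor((values - anchor) / bin_width) + 1L
  storage.mode(bins) <- "integer"
  list(bins = bins, histogram = tabulate(bins, nbins = max(bins)),
       n_levels = max(bins))
}

# type-7 quantiles per group over values sorted within group.
# sv: sorted values; start/n per group; p scalar probability.
grouped_quantile <- function(sv, start, n, p) {
  h <- (n - 1) * p
  lo <- floor(h)
  fr <- h - lo
  x <- sv[start + lo]
  hi_ok <- fr > 0
  x[hi_ok] <- x[hi_ok] * (1 - fr[hi_ok]) + sv[start + lo + 1][hi_ok] * fr[hi_ok]
  x
}

#' First-order features for many regions at once
#'
#' @param values numeric vector of voxel intensities.
#' @param group integer group id (1..G) per value; every group non-empty.
#' @param bin_width discretisation width for entropy/uniformity.
#' @param voxel_volume_mm3 voxel volume used by total energy.
#' @return G x 19 matrix with columns `FO_NAMES`.
#' @export
first_order_grouped <- function(values, group, bin_width = 25, voxel_volume_mm3 = 1) {
  G <- max(group)
  n <- tabulate(group, nbins = G)
  if (any(n == 0)) stop_domain("every group must contain at least one voxel")
  o <- order(group, values)
  sv <- values[o]
  cum <- cumsum(n)
  start <- cum - n + 1L

  s1 <- rowsum(values, group, reorder = TRUE)[, 1]
  mu <- s1 / n
  cent <- values - mu[group]
  m2 <- rowsum(cent^2, group)[, 1] / n
  m3 <- rowsum(cent^3, group)[, 1] / n
  m4 <- rowsum(cent^4, group)[, 1] / n
  energy <- rowsum(values^2, group)[, 1]
  mad <- rowsum(abs(cent), group)[, 1] / n

  minimum <- sv[start]
  maximum <- sv[cum]
  p10 <- grouped_quantile(sv, start, n, 0.10)
  p90 <- grouped_quantile(sv, start, n, 0.90)
  p25 <- grouped_quantile(sv, start, n, 0.25)
  p75 <- grouped_quantile(sv, start, n, 0.75)
  med <- grouped_quantile(sv, start, n, 0.50)

  # robust MAD on the 10-90 percentile sub-range
  inw <- values >= p10[group] & values <= p90[group]
  nw <- rowsum(as.numeric(inw), group)[, 1]
  sw <- rowsum(values * inw, group)[, 1]
  muw <- ifelse(nw > 0, sw / nw, 0)
  rmad <- ifelse(nw > 0,
                 rowsum(abs(values - muw[group]) * inw, group)[, 1] / pmax(nw, 1),
                 0)

  # histogram entropy / uniformity, anchored at the group minimum
  bins <- floor((values - minimum[group]) / bin_width)
  maxb <- max(bins) + 1L
  key <- (group - 1L) * maxb + bins + 1L
  cnt <- tabulate(key, nbins = G * maxb)
  nz <- which(cnt > 0)
  gk <- (nz - 1L) %/% maxb + 1L
  pk <- cnt[nz] / n[gk]
  entropy <- rep(0, G)
  uniformity <- rep(0, G)
  ent_part <- rowsum(-pk * log2(pk), gk)
  uni_part <- rowsum(pk^2, gk)
  entropy[as.integer(rownames(ent_part))] <- ent_part[, 1]
  uniformity[as.integer(rownames(uni_part))] <- uni_part[, 1]

  variance <- m2
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2, 0)

  out <- cbind(energy, energy * voxel_volume_mm3, entropy, minimum, p10, p90,
               maximum, mu, med, p75 - p25, maximum - minimum, mad, rmad,
               sqrt(energy / n), sqrt(variance), variance, skew, kurt, uniformity)
  colnames(out) <- FO_NAMES
  out
}

#' First-order features of a single region
#'
#' The 19-member intensity/histogram family: energy, total energy, histogram
#' entropy (bits), minimum, 10th/90th percentiles, maximum, mean, median,
#' interquartile range, range, mean absolute deviation, robust MAD (10-90%
#' sub-range), root mean squared, standard deviation, population variance,
#' skewness, kurtosis (Fisher + 3 convention) and uniformity. Skewness and
#' kurtosis are defined as 0 for regions without at least two distinct values.
#'
#' @inheritParams first_order_grouped
#' @return Named numeric vector of length 19.
#' @export
first_order_features <- function(values, bin_width = 25, voxel_volume_mm3 = 1) {
  if (length(values) == 0) stop_domain("empty region")
  first_order_grouped(values, rep(1L, length(values)), bin_width, voxel_volume_mm3)[1, ]
}
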