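# Higher-order texture features over the fixed-bin-width discretised region:
# grey-level co-occurrence (GLCM, 22), run length (GLRLM, 16), size zone
# (GLSZM, 16), dependence (GLDM, 12) and neighbourhood tone difference
# (NGTDM, 5). Co-occurrence and run matrices are accumulated over the 13
# unique 3-D directions at distance 1 and the features averaged across
# directions; zone/dependence/tone statistics use the full 26-neighbourhood.
# Degenerate regions (a single grey level) take each family's closed-form
# values rather than NaN; notably GLCM correlation is defined as 1.

GLCM_NAMES <- paste0("glcm_", c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "joint_energy", "joint_entropy",
  "imc1", "imc2", "idm", "idmn", "id", "idn", "inverse_variance",
  "maximum_probability", "sum_entropy", "sum_squares"))

GLRLM_NAMES <- paste0("glrlm_", c(
  "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "run_length_nonuniformity",
  "run_length_nonuniformity_normalized", "run_percentage",
  "gray_level_variance", "run_variance", "run_entropy",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis"))

GLSZM_NAMES <- paste0("glszm_", c(
  "small_area_emphasis", "large_area_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "size_zone_nonuniformity",
  "size_zone_nonuniformity_normalized", "zone_percentage",
  "gray_level_variance", "zone_variance", "zone_entropy",
  "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
  "small_area_low_gray_level_emphasis", "small_area_high_gray_level_emphasis",
  "large_area_low_gray_level_emphasis", "large_area_high_gray_level_emphasis"))

GLDM_NAMES <- paste0("gldm_", c(
  "small_dependence_emphasis", "large_dependence_emphasis",
  "gray_level_nonuniformity", "dependence_nonuniformity",
  "dependence_nonuniformity_normalized", "gray_level_variance",
  "dependence_variance", "dependence_entropy", "low_gray_level_emphasis",
  "high_gray_level_emphasis", "small_dependence_low_gray_level_emphasis",
  "large_dependence_high_gray_level_emphasis"))

NGTDM_NAMES <- paste0("ngtdm_", c(
  "coarseness", "contrast", "busyness", "complexity", "strength"))

glcm_features_one <- function(M, ng) {
  P <- M + t(M)
  tot <- sum(P)
  if (tot == 0) return(setNames(rep(NA_real_, 22), GLCM_NAMES))
  P <- P / tot
  I <- row(P); J <- col(P)
  px <- rowSums(P)
  mu <- sum(I * P)
  sigma2 <- sum((I - mu)^2 * P)
  k_diff <- abs(I - J)
  pd <- rowsum(as.vector(P), as.vector(k_diff))      # p_{|x-y|}, names 0..ng-1
  kd <- as.numeric(rownames(pd)); pd <- pd[, 1]
  ks <- as.vector(I + J)
  psum <- rowsum(as.vector(P), ks)
  kv <- as.numeric(rownames(psum)); psum <- psum[, 1]

  da <- sum(kd * pd)
  nzd <- pd > 0
  de <- -sum(pd[nzd] * log2(pd[nzd]))
  dv <- sum((kd - da)^2 * pd)
  nz <- P > 0
  hxy <- -sum(P[nz] * log2(P[nz]))
  pxi <- px[I[nz]]; pyj <- px[J[nz]]
  hxy1 <- -sum(P[nz] * log2(pxi * pyj))
  op <- outer(px, px)
  onz <- op > 0
  hxy2 <- -sum(op[onz] * log2(op[onz]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  corr <- if (sigma2 > 0) (sum(I * J * P) - mu^2) / sigma2 else 1
  offdiag <- I != J
  nzs <- psum > 0

  c(sum(I * J * P), mu,
    sum((I + J - 2 * mu)^4 * P), sum((I + J - 2 * mu)^3 * P),
    sum((I + J - 2 * mu)^2 * P),
    sum((I - J)^2 * P), corr, da, de, dv,
    sum(P^2), hxy,
    if (hx > 0) (hxy - hxy1) / hx else 0,
    sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    sum(P / (1 + (I - J)^2)), sum(P / (1 + (I - J)^2 / ng^2)),
    sum(P / (1 + abs(I - J))), sum(P / (1 + abs(I - J) / ng)),
    sum(P[offdiag] / (I[offdiag] - J[offdiag])^2),
    max(P), -sum(psum[nzs] * log2(psum[nzs])), sigma2)
}

glrlm_features_one <- function(M, np) {
  nr <- sum(M)
  i <- row(M); l <- col(M)
  p <- M / nr
  ri <- rowSums(M); cl <- colSums(M)
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  nz <- p > 0
  c(sum(M / l^2) / nr, sum(M * l^2) / nr,
    sum(ri^2) / nr, sum(ri^2) / nr^2,
    sum(cl^2) / nr, sum(cl^2) / nr^2,
    nr / np,
    sum((i - mu_i)^2 * p), sum((l - mu_l)^2 * p),
    -sum(p[nz] * log2(p[nz])),
    sum(p / i^2), sum(p * i^2),
    sum(p / (i^2 * l^2)), sum(p * i^2 / l^2),
    sum(p * l^2 / i^2), sum(p * i^2 * l^2))
}

glszm_features <- function(level, size, np) {
  nz <- length(size)
  i <- level; s <- size
  p <- rep(1 / nz, nz)                     # each zone one count
  ri <- tapply(rep(1, nz), i, sum)         # zones per level
  cs <- tapply(rep(1, nz), s, sum)         # zones per size
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  # zone entropy over distinct (level, size) cells
  cell <- table(paste(i, s))
  pc <- as.numeric(cell) / nz
  out <- c(sum(1 / s^2) / nz, sum(s^2) / nz,
           sum(ri^2) / nz, sum(ri^2) / nz^2,
           sum(cs^2) / nz, sum(cs^2) / nz^2,
           nz / np,
           sum((i - mu_i)^2 * p), sum((s - mu_s)^2 * p),
           -sum(pc * log2(pc)),
           sum(p / i^2), sum(p * i^2),
           sum(1 / (i^2 * s^2)) / nz, sum(i^2 / s^2) / nz,
           sum(s^2 / i^2) / nz, sum(i^2 * s^2) / nz)
  setNames(out, GLSZM_NAMES)
}

gldm_features <- function(M) {
  n <- sum(M)
  i <- row(M); d <- col(M)
  p <- M / n
  ri <- rowSums(M); cd <- colSums(M)
  mu_i <- sum(i * p); mu_d <- sum(d * p)
  nz <- p > 0
  out <- c(sum(M / d^2) / n, sum(M * d^2) / n,
           sum(ri^2) / n, sum(cd^2) / n, sum(cd^2) / n^2,
           sum((i - mu_i)^2 * p), sum((d - mu_d)^2 * p),
           -sum(p[nz] * log2(p[nz])),
           sum(p / i^2), sum(p * i^2),
           sum(M / (i^2 * d^2)) / n, sum(M * i^2 * d^2) / n)
  setNames(out, GLDM_NAMES)
}

ngtdm_features <- function(ni, si) {
  N <- sum(ni)
  present <- which(ni > 0)
  pv <- ni[present] / N
  sv <- si[present]
  iv <- present
  ngp <- length(present)
  coarse_den <- sum(pv * sv)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(pv, pv) * outer(iv, iv, "-")^2) / (ngp * (ngp - 1))) * (sum(sv) / N)
  } else 0
  ipi <- iv * pv
  bus_den <- sum(abs(outer(ipi, ipi, "-")))
  busyness <- if (bus_den > 0) coarse_den / bus_den else 0
  PI <- outer(pv, pv, "+")
  num_c <- abs(outer(iv, iv, "-")) * (outer(pv * sv, rep(1, ngp)) + outer(rep(1, ngp), pv * sv)) / PI
  complexity <- sum(num_c) / N
  str_num <- sum(PI * outer(iv, iv, "-")^2)
  strength <- if (sum(sv) > 0) str_num / sum(sv) else 0
  setNames(c(coarseness, contrast, busyness, complexity, strength), NGTDM_NAMES)
}

#' Higher-order texture features of a region
#'
#' @param volume an [image_volume] or numeric 3-D array.
#' @param mask logical 3-D array of the same shape, >= 27 voxels.
#' @param bin_width fixed bin width for discretisation (HU).
#' @return Named numeric vector of 71 features (22 GLCM + 16 GLRLM + 16 GLSZM
#'   + 12 GLDM + 5 NGTDM).
#' @export
texture_features <- function(volume, mask, bin_width = 25) {
  vox <- if (inherits(volume, "image_volume")) volume$voxels else volume
  if (!identical(dim(vox), dim(mask))) stop_domain("volume and mask shapes differ")
  if (sum(mask) < 27) stop_domain("texture features need a mask of >= 27 voxels")
  vals <- vox[mask]
  disc <- discretize(vals, bin_width)
  ng <- disc$n_levels
  arr <- array(0L, dim(vox))
  arr[mask] <- disc$bins
  np <- length(vals)
  dims <- as.integer(dim(vox))

  glcm_list <- glcm_cpp(as.integer(arr), dims, ng)
  glcm <- rowMeans(vapply(glcm_list, glcm_features_one, numeric(22), ng = ng))
  names(glcm) <- GLCM_NAMES

  glrlm_list <- glrlm_cpp(as.integer(arr), dims, ng)
  glrlm <- rowMeans(vapply(glrlm_list, glrlm_features_one, numeric(16), np = np))
  names(glrlm) <- GLRLM_NAMES

  zones <- glszm_cpp(as.integer(arr), dims)
  glszm <- glszm_features(zones$level, zones$size, np)

  gldm <- gldm_features(gldm_cpp(as.integer(arr), dims, ng))

  nt <- ngtdm_cpp(as.integer(arr), dims, ng)
  ngtdm <- ngtdm_features(nt$n, nt$s)

  c(glcm, glrlm, glszm, gldm, ngtdm)
}
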