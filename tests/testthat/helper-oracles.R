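# Independent brute-force oracles, written from the definitions with plain
# loops. They share no code with the package's vectorised/C++ paths.

oracle_first_order <- function(v, bin_width = 25, voxvol = 1) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  q <- function(p) unname(quantile(v, p, type = 7))
  # histogram with fixed-width bins anchored at the minimum
  b <- floor((v - min(v)) / bin_width) + 1
  pb <- as.numeric(table(b)) / n
  p10 <- q(0.1); p90 <- q(0.9)
  sub <- v[v >= p10 & v <= p90]
  rmad <- if (length(sub)) mean(abs(sub - mean(sub))) else 0
  c(fo_energy = sum(v^2),
    fo_total_energy = sum(v^2) * voxvol,
    fo_entropy = -sum(pb * log2(pb)),
    fo_minimum = min(v), fo_p10 = p10, fo_p90 = p90, fo_maximum = max(v),
    fo_mean = mu, fo_median = q(0.5),
    fo_iqr = q(0.75) - q(0.25), fo_range = max(v) - min(v),
    fo_mad = mean(abs(v - mu)), fo_rmad = rmad,
    fo_rms = sqrt(mean(v^2)), fo_sd = sqrt(m2), fo_variance = m2,
    fo_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    fo_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    fo_uniformity = sum(pb^2))
}

# all 26 neighbour offsets split into the 13 canonical directions + negations
oracle_directions <- function() {
  d <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
            c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
            c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  d
}

# symmetric co-occurrence matrix for one direction by direct pair counting
oracle_glcm_matrix <- function(bins, dir) {
  ng <- max(bins)
  d <- dim(bins)
  M <- matrix(0, ng, ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- bins[x, y, z]
    if (a == 0) next
    xx <- x + dir[1]; yy <- y + dir[2]; zz <- z + dir[3]
    if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
    b <- bins[xx, yy, zz]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# all 22 GLCM features computed from a normalised symmetric matrix with plain
# accumulation loops, written directly from the definitions
oracle_glcm_features <- function(P, ng) {
  P <- P / sum(P)
  px <- rowSums(P)
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  s2 <- 0
  for (i in 1:ng) s2 <- s2 + (i - mu)^2 * px[i]
  pdiff <- rep(0, ng)          # |i-j| in 0..ng-1
  psum <- rep(0, 2 * ng - 1)   # i+j in 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
    psum[i + j - 1] <- psum[i + j - 1] + P[i, j]
  }
  f <- c(autocorrelation = 0, joint_average = mu, cluster_prominence = 0,
         cluster_shade = 0, cluster_tendency = 0, contrast = 0, correlation = 0,
         difference_average = 0, difference_entropy = 0, difference_variance = 0,
         joint_energy = 0, joint_entropy = 0, imc1 = 0, imc2 = 0, idm = 0,
         idmn = 0, id = 0, idn = 0, inverse_variance = 0,
         maximum_probability = max(P), sum_entropy = 0, sum_squares = s2)
  hxy <- 0; hxy1 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f["autocorrelation"] <- f["autocorrelation"] + i * j * p
    f["cluster_prominence"] <- f["cluster_prominence"] + (i + j - 2 * mu)^4 * p
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - 2 * mu)^3 * p
    f["cluster_tendency"] <- f["cluster_tendency"] + (i + j - 2 * mu)^2 * p
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    f["joint_energy"] <- f["joint_energy"] + p^2
    if (p > 0) {
      hxy <- hxy - p * log2(p)
      hxy1 <- hxy1 - p * log2(px[i] * px[j])
    }
    f["idm"] <- f["idm"] + p / (1 + (i - j)^2)
    f["idmn"] <- f["idmn"] + p / (1 + (i - j)^2 / ng^2)
    f["id"] <- f["id"] + p / (1 + abs(i - j))
    f["idn"] <- f["idn"] + p / (1 + abs(i - j) / ng)
    if (i != j) f["inverse_variance"] <- f["inverse_variance"] + p / (i - j)^2
  }
  f["joint_entropy"] <- hxy
  f["correlation"] <- if (s2 > 0) (f[["autocorrelation"]] - mu^2) / s2 else 1
  for (k in 0:(ng - 1)) {
    p <- pdiff[k + 1]
    f["difference_average"] <- f["difference_average"] + k * p
    if (p > 0) f["difference_entropy"] <- f["difference_entropy"] - p * log2(p)
  }
  for (k in 0:(ng - 1))
    f["difference_variance"] <- f["difference_variance"] +
      (k - f[["difference_average"]])^2 * pdiff[k + 1]
  for (k in seq_along(psum))
    if (psum[k] > 0) f["sum_entropy"] <- f["sum_entropy"] - psum[k] * log2(psum[k])
  hx <- 0; hxy2 <- 0
  for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  for (i in 1:ng) for (j in 1:ng)
    if (px[i] * px[j] > 0) hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j])
  f["imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  f["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  f
}

# information gain by direct entropy computation over given bin memberships
oracle_information_gain <- function(bins, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  hy <- ent(y)
  hc <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    hc <- hc + mean(sel) * ent(y[sel])
  }
  hy - hc
}

# exact two-sided Mann-Whitney p by explicit enumeration over combinations
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  ustat <- function(ix) sum(r[ix]) - nx * (nx + 1) / 2
  obs <- ustat(seq_len(nx))
  all_u <- apply(combn(nx + ny, nx), 2, ustat)
  min(1, 2 * min(mean(all_u <= obs), mean(all_u >= obs)))
}

# random small region fixture: correlated-ish values on a small grid with a
# random blob mask
random_region <- function(seed, side = 6) {
  set.seed(seed)
  arr <- array(rnorm(side^3, mean = 100, sd = 25), dim = rep(side, 3))
  centre <- runif(3, 2.5, side - 1.5)
  rad <- runif(1, 2.2, side / 2)
  co <- as.matrix(expand.grid(x = 1:side, y = 1:side, z = 1:side))
  mask <- array(sqrt(colSums((t(co) - centre)^2)) <= rad, dim = rep(side, 3))
  if (sum(mask) < 27) mask <- array(TRUE, dim = rep(side, 3))
  list(arr = arr, mask = mask)
}
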