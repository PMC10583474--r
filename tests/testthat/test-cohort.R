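test_that("Mann-Whitney U matches exact enumeration and conserves U", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")
  # same multiset in both samples: U = n^2 / 2
  x <- c(1, 5, 9, 2)
  expect_equal(mann_whitney_u(x, x)$U, 8)
  # conservation across random samples with ties
  set.seed(14)
  for (i in 1:15) {
    a <- sample(1:6, sample(3:8, 1), replace = TRUE)
    b <- sample(1:6, sample(3:8, 1), replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U,
                 length(a) * length(b))
  }
  # exact path agrees with the independent enumeration oracle
  for (i in 1:10) {
    a <- sample(1:9, 5, replace = TRUE)
    b <- sample(1:9, 5, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p, oracle_mw_exact(a, b), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact and approximate Mann-Whitney p agree at the enumeration boundary", {
  set.seed(15)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6, 0.5)       # n1 + n2 = 12, no ties
    p_exact <- mann_whitney_u(a, b)$p
    # recompute the normal approximation directly on the original data
    r <- rank(c(a, b)); U <- sum(r[1:6]) - 21
    z <- (U - 18 - sign(U - 18) * 0.5) / sqrt(6 * 6 * 13 / 12)
    p_approx <- min(1, 2 * pnorm(-abs(z)))
    expect_lte(abs(p_exact - p_approx), 0.02)
  }
})

test_that("chi-square and Spearman match hand examples and symmetries", {
  flat <- matrix(10, 2, 2)
  cs <- chi_square(flat)
  expect_equal(cs$stat, 0)
  expect_equal(cs$p, 1)
  skew <- matrix(c(20, 10, 10, 20), 2, 2)
  cs2 <- chi_square(skew)
  expect_equal(cs2$stat, 20 / 3, tolerance = 1e-9)
  expect_equal(cs2$df, 1)
  expect_equal(chi_square(t(skew))$stat, cs2$stat)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")

  expect_equal(spearman_rho(1:8, (1:8)^3), 1)
  expect_equal(spearman_rho(1:8, -(1:8)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(rep(2, 5), 1:5), "constant")
})

test_that("Shapiro-Wilk screening is bounded, calibrated, and flags bimodality", {
  set.seed(16)
  for (i in 1:10) expect_lte(shapiro_wilk(rnorm(30))$W, 1)
  rejections <- mean(vapply(1:200, function(i) shapiro_wilk(rnorm(50))$p < 0.05,
                            logical(1)))
  expect_gte(rejections, 0.01)
  expect_lte(rejections, 0.12)
  bimodal <- c(rnorm(50, -8), rnorm(50, 8))
  expect_lt(shapiro_wilk(bimodal)$p, 0.01)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("ROC curves handle orientation, ties and the AUC/U identity", {
  r1 <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0), "higher")
  expect_equal(r1$auc, 1)
  r2 <- roc_auc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1), "higher")
  expect_equal(r2$auc, 0.75)
  expect_equal(roc_auc(rep(2, 6), c(1, 0, 1, 0, 0, 1))$auc, 0.5)
  # lower-is-positive flips the orientation
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(0, 0, 1, 1), "lower")$auc, 1)
  # curve endpoints and monotonicity
  expect_equal(r2$tpr[1], 0)
  expect_equal(r2$fpr[1], 0)
  expect_equal(tail(r2$tpr, 1), 1)
  expect_equal(tail(r2$fpr, 1), 1)
  expect_true(all(diff(r2$tpr) >= 0) && all(diff(r2$fpr) >= 0))
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  # AUC equals U / (n1 n2) with mid-rank ties, on 100 random score sets
  set.seed(17)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # heavy ties
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lb) || all(lb)) next
    auc <- roc_auc(sc, lb, "higher")$auc
    u_pos <- mann_whitney_u(sc[lb], sc[!lb])$U
    expect_equal(auc, u_pos / (sum(lb) * sum(!lb)), tolerance = 1e-12)
  }
})

test_that("primary outcome ranks a perfect predictor and handles degenerate groups", {
  # synthetic volumetry records where PHLF is a deterministic FRFxV threshold
  set.seed(18)
  n <- 30
  rec <- data.frame(
    phlf_grade = character(n), technique = rep(c("ALPPS", "PVE"), 15),
    frl_post_cc = runif(n, 500, 1600), frfx_post_cc = runif(n, 150, 1500),
    frlv_pct = runif(n, 30, 120), frfxv_pct = runif(n, 5, 110),
    ifrl_pct = runif(n, 10, 240), ifrfx_pct = runif(n, -70, 160),
    sflr_pct = runif(n, 40, 120), kgr_pct_per_day = runif(n, 0, 5),
    stringsAsFactors = FALSE)
  rec$phlf_grade <- ifelse(rec$frfxv_pct < quantile(rec$frfxv_pct, 0.25), "B", "none")
  out <- primary_outcome(rec)
  expect_equal(out$auc$auc[out$auc$predictor == "frfxv_pct"], 1)
  expect_equal(out$n_severe + out$n_mild, n)
  expect_identical(out$table$variable,
                   c("frl_post_cc", "frfx_post_cc", "frlv_pct", "frfxv_pct",
                     "ifrl_pct", "ifrfx_pct", "sflr_pct", "kgr_pct_per_day"))
  # degenerate outcome group -> NA with a warning, not an error
  rec2 <- rec; rec2$phlf_grade <- c("B", rep("none", n - 1))
  expect_warning(out2 <- primary_outcome(rec2), "fewer than 2")
  expect_true(all(is.na(out2$auc$auc)))
})

test_that("outcome-independent predictors score near-chance AUCs", {
  set.seed(19)
  n <- 200
  rec <- data.frame(
    phlf_grade = sample(c("none", "A", "B", "C"), n, replace = TRUE,
                        prob = c(0.55, 0.2, 0.17, 0.08)),
    technique = sample(c("ALPPS", "PVE"), n, replace = TRUE),
    frl_post_cc = runif(n, 500, 1600), frfx_post_cc = runif(n, 150, 1500),
    frlv_pct = runif(n, 30, 120), frfxv_pct = runif(n, 5, 110),
    ifrl_pct = runif(n, 10, 240), ifrfx_pct = runif(n, -70, 160),
    sflr_pct = runif(n, 40, 120), kgr_pct_per_day = runif(n, 0, 5),
    stringsAsFactors = FALSE)
  out <- primary_outcome(rec)
  expect_true(all(out$auc$auc > 0.35 & out$auc$auc < 0.65))
})

test_that("secondary outcome emits the full per-technique contrast table", {
  set.seed(20)
  n <- 24
  rec <- data.frame(
    technique = rep(c("ALPPS", "PVE"), c(11, 13)),
    tlv_cc = runif(n, 1100, 1700), frl_pre_cc = runif(n, 250, 900),
    frfx_pre_cc = runif(n, 220, 850), frlv_pre_pct = runif(n, 19, 68),
    frfxv_pre_pct = runif(n, 16, 60), frl_post_cc = runif(n, 530, 1660),
    frfx_post_cc = runif(n, 120, 1500), frlv_pct = runif(n, 29, 127),
    frfxv_pct = runif(n, 3, 117), ifrl_pct = runif(n, 15, 242),
    ifrfx_pct = runif(n, -79, 166), stringsAsFactors = FALSE)
  out <- secondary_outcome(rec)
  expect_identical(out$variable,
                   c("tlv_cc", "frl_pre_cc", "frfx_pre_cc", "frlv_pre_pct",
                     "frfxv_pre_pct", "frl_post_cc", "frfx_post_cc", "frlv_pct",
                     "frfxv_pct", "ifrl_pct", "ifrfx_pct"))
  expect_true(all(out$p >= 0 & out$p <= 1))
  # exchangeable arms: contrasts centred on zero across replicates
  diffs <- vapply(1:30, function(r) {
    set.seed(400 + r)
    v <- runif(n, 10, 240)
    g <- rep(c("ALPPS", "PVE"), c(11, 13))
    median(v[g == "ALPPS"]) - median(v[g == "PVE"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 25)
  expect_error(secondary_outcome(rec[rec$technique == "PVE", ]), "both techniques")
})

test_that("the Rand index agrees with direct pair counting", {
  set.seed(22)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  got <- frfx:::rand_index(a, b)
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  expect_equal(got, mean(same_a == same_b), tolerance = 1e-12)
  expect_equal(frfx:::rand_index(a, a), 1)
})
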