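test_that("information gain respects its bounds and closed forms", {
  set.seed(21)
  y <- rep(c("a", "b"), each = 1000)
  # statistically identical feature carries almost no information
  x_null <- rnorm(2000)
  expect_lt(information_gain(x_null, y), 0.02)
  # perfectly separating feature on balanced classes carries exactly 1 bit
  x_sep <- c(rnorm(1000, -10), rnorm(1000, 10))
  expect_equal(information_gain(x_sep, y, n_bins = 2), 1, tolerance = 1e-12)
  # bounds and monotone-transform invariance
  x <- rnorm(400); yy <- rep(c("a", "b"), 200)
  ig <- information_gain(x, yy)
  expect_gte(ig, 0)
  expect_lte(ig, 1)
  expect_equal(information_gain(exp(2 * x), yy), ig, tolerance = 1e-12)
  expect_error(information_gain(x, rep("a", 400)), "2 classes")
})

test_that("an 8-point information-gain example matches exhaustive entropy computation", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  got <- information_gain(x, y, n_bins = 4)
  # reproduce the fixed equal-frequency binning, then brute-force the entropies
  br <- unique(quantile(x, seq(0, 1, 0.25), type = 7, names = FALSE))
  bins <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  expect_equal(got, oracle_information_gain(bins, y), tolerance = 1e-12)
})

test_that("pooled-variance t screening matches the closed form and is antisymmetric", {
  m <- cbind(f = c(1, 2, 3, 4, 3, 4, 5, 6))
  lab <- rep(c("A", "B"), each = 4)
  out <- screen_ttest(m, lab)
  expect_equal(out$t, -2.19089023, tolerance = 1e-7)
  expect_equal(out$p, 2 * pt(-2.19089023, df = 6), tolerance = 1e-7)
  out_sw <- screen_ttest(m, rev(lab))
  expect_equal(out_sw$t, -out$t, tolerance = 1e-12)
  # identical groups give t = 0, p = 1; constant separated groups hit the sentinel
  m2 <- cbind(same = rep(c(5, 6), 4), const = rep(7, 8))
  out2 <- screen_ttest(m2, lab)
  expect_equal(out2$t[out2$feature == "const"], 0)
  expect_equal(out2$p[out2$feature == "const"], 1)
  m3 <- cbind(k = rep(c(0, 1), each = 4))
  out3 <- screen_ttest(m3, lab)
  expect_true(is.infinite(out3$t))
  expect_equal(out3$p, 0)
})

test_that("k-means recovers separated blobs and nests inertia", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 10), ncol = 2))
  km2 <- kmeans_profiles(x, k = 2, seed = 3L)
  truth <- rep(1:2, each = 30)
  agree <- max(mean(km2$assignments == truth), mean(km2$assignments == 3 - truth))
  expect_equal(agree, 1)
  km1 <- kmeans_profiles(x, k = 1, seed = 3L)
  expect_equal(drop(km1$centroids), colMeans(x), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(km1$inertia, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-9)
  expect_lte(km2$inertia, km1$inertia)
  expect_identical(kmeans_profiles(x, 2, seed = 8L)$assignments,
                   kmeans_profiles(x, 2, seed = 8L)$assignments)
  expect_error(kmeans_profiles(x[1:3, ], k = 5), "exceed")
})

test_that("penalised logistic regression separates, recovers and stays in (0,1)", {
  set.seed(6)
  # linearly separable toy set
  xs <- cbind(a = c(rnorm(40, -3), rnorm(40, 3)))
  ys <- rep(c(0, 1), each = 40)
  m <- fit_logistic(xs, ys, l2_strength = 1)
  acc <- mean((predict_logistic(m, xs) >= 0.5) == ys)
  expect_equal(acc, 1)
  p <- predict_logistic(m, xs)
  expect_true(all(p > 0 & p < 1))
  # coefficient recovery from a known logistic model at weak penalty
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  eta <- 1 * X[, 1] - 2 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(X, y, l2_strength = 1e-3)
  expect_equal(unname(fit$coefficients["x1"]), 1, tolerance = 0.15)
  expect_equal(unname(fit$coefficients["x2"]), -2, tolerance = 0.15 / 2)
  expect_true(fit$converged)
})

test_that("training selects informative first-order features and reports cleanly", {
  fit <- fixture_model()
  sel <- fit$selection
  expect_equal(nrow(sel), 19)
  ranked <- sel[!is.na(sel$rank), ]
  expect_true(all(diff(ranked$info_gain[order(ranked$rank)]) <= 1e-12))
  expect_true(all(sel$info_gain >= 0))
  # extensive features are reported but never candidates at patch level
  expect_setequal(sel$feature[!sel$candidate], c("fo_energy", "fo_total_energy"))
  chosen <- sel$feature[sel$selected]
  expect_length(chosen, 5)
  expect_true(any(c("fo_mean", "fo_variance") %in% chosen))
  expect_true(all(startsWith(chosen, "fo_")))
  expect_s3_class(fit$model, "logistic_model")
  expect_gte(fit$kmeans_rand_index, 0)
  expect_lte(fit$kmeans_rand_index, 1)
})

test_that("patch classification recovers functional volume across the theta range", {
  fit <- fixture_model()
  ratios <- vapply(c(0, 0.5), function(th) {
    sp <- default_sim_params("ALPPS"); sp$theta <- th
    cs <- generate_case(sp, seed = 300L + round(100 * th), images = "post")
    am <- flr_analysis_mask(cs$post$seg)
    fm <- classify_patches(cs$post$image, am, fit$model)
    expect_true(all(fm$prob[!is.na(fm$prob)] >= 0 & fm$prob[!is.na(fm$prob)] <= 1))
    fm$frfx_cc / mask_volume_cc(cs$post$seg$observed, 2L, cs$post$seg$spacing)
  }, numeric(1))
  expect_gte(ratios[1], 0.9)   # theta = 0: estimate within 10% of FRL
  expect_lte(ratios[1], 1.02)
  expect_gte(ratios[2], 0.4)   # theta = 0.5: about half functional
  expect_lte(ratios[2], 0.6)
})

test_that("estimated functional fraction decreases monotonically in theta", {
  fit <- fixture_model()
  ratios <- vapply(c(0, 0.25, 0.5, 0.75), function(th) {
    sp <- default_sim_params("PVE"); sp$theta <- th
    cs <- generate_case(sp, seed = 600L + round(100 * th))
    est <- estimate_frfx(cs, fit$model)
    # pre study is all functional
    frl_pre <- mask_volume_cc(cs$pre$seg$observed, 2L, cs$pre$seg$spacing)
    expect_gte(est[["frfx_pre_cc"]] / frl_pre, 0.9)
    est[["frfx_post_cc"]] / mask_volume_cc(cs$post$seg$observed, 2L, cs$post$seg$spacing)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("classification is deterministic given a fixed model and case", {
  fit <- fixture_model()
  cs <- fixture_case()
  am <- flr_analysis_mask(cs$post$seg)
  f1 <- classify_patches(cs$post$image, am, fit$model)
  f2 <- classify_patches(cs$post$image, am, fit$model)
  expect_identical(f1, f2)
})
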