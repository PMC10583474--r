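test_that("fixed-bin discretisation follows the floor rule and conserves counts", {
  d <- discretize(c(0, 24.9, 25, 50), bin_width = 25, anchor = 0)
  expect_equal(d$bins, c(1L, 1L, 2L, 3L))
  expect_equal(sum(d$histogram), 4)
  dc <- discretize(rep(7.3, 10), bin_width = 5)
  expect_equal(dc$n_levels, 1)
  set.seed(2)
  v <- rnorm(500, 100, 30)
  expect_equal(sum(discretize(v, 25)$histogram), 500)
  expect_error(discretize(numeric(0), 25), "empty")
})

test_that("first-order features match their closed forms", {
  f <- first_order_features(c(1, 2, 3, 4), bin_width = 1)
  expect_equal(unname(f["fo_mean"]), 2.5)
  expect_equal(unname(f["fo_variance"]), 1.25)
  expect_equal(unname(f["fo_rms"]), sqrt(7.5), tolerance = 1e-6)
  expect_equal(unname(f["fo_energy"]), 30)
  expect_equal(unname(f["fo_entropy"]), 2)       # four equiprobable bins
  expect_equal(unname(f["fo_uniformity"]), 0.25)

  fc <- first_order_features(rep(12, 50))
  expect_equal(unname(fc["fo_variance"]), 0)
  expect_equal(unname(fc["fo_entropy"]), 0)
  expect_equal(unname(fc["fo_uniformity"]), 1)
  expect_equal(unname(fc[c("fo_mean", "fo_median", "fo_minimum", "fo_maximum")]),
               rep(12, 4))
  expect_equal(unname(fc["fo_skewness"]), 0)
  expect_equal(unname(fc["fo_kurtosis"]), 0)
})

test_that("first-order features agree with the brute-force oracle on random regions", {
  for (s in 1:10) {
    set.seed(s)
    v <- rnorm(40 + 10 * s, 100, 25)
    got <- first_order_features(v, bin_width = 25, voxel_volume_mm3 = 15.625)
    want <- oracle_first_order(v, bin_width = 25, voxvol = 15.625)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
})

test_that("the grouped first-order path equals per-group scalar computation", {
  set.seed(9)
  v <- rnorm(600, 80, 30)
  g <- sample(1:7, 600, replace = TRUE)
  fm <- first_order_grouped(v, g, bin_width = 20, voxel_volume_mm3 = 2)
  for (k in c(1, 4, 7)) {
    expect_equal(fm[k, ], first_order_features(v[g == k], bin_width = 20,
                                               voxel_volume_mm3 = 2),
                 tolerance = 1e-10)
  }
})

test_that("shape features are accurate on analytic solids", {
  side <- 25
  co <- as.matrix(expand.grid(1:side, 1:side, 1:side))
  ball <- array(sqrt(colSums((t(co) - 13)^2)) <= 10, dim = rep(side, 3))
  sf <- shape_features(ball, c(1, 1, 1))
  expect_gte(unname(sf["sh_sphericity"]), 0.95)
  expect_lte(unname(sf["sh_sphericity"]), 1.0)
  expect_equal(unname(sf["sh_mesh_volume"]), 4 / 3 * pi * 1000, tolerance = 0.05)
  expect_equal(unname(sf["sh_max_3d_diameter"]), 20, tolerance = 0.05)
  expect_equal(unname(sf["sh_elongation"]), 1, tolerance = 1e-2)

  cube <- array(FALSE, dim = c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- TRUE
  cf <- shape_features(cube, c(1, 1, 1))
  expect_equal(unname(cf["sh_voxel_volume"]), 1000)
  expect_equal(unname(cf["sh_elongation"]), 1, tolerance = 1e-6)
  expect_equal(unname(cf["sh_flatness"]), 1, tolerance = 1e-6)

  single <- array(FALSE, dim = c(8, 8, 8)); single[4, 4, 4] <- TRUE
  expect_warning(s1 <- shape_features(single, c(1, 1, 1)), "degenerate")
  expect_true(attr(s1, "degenerate"))
})

test_that("GLCM features match hand-counted co-occurrence on the 121212 pattern", {
  arr <- array(0, dim = c(6, 3, 3))
  arr[, 1, 1] <- c(1, 2, 1, 2, 1, 2) * 25 - 25   # values 0/25 -> bins 1/2
  mask <- array(FALSE, dim = c(6, 3, 3)); mask[, 1, 1] <- TRUE
  bins <- array(0L, dim = c(6, 3, 3)); bins[mask] <- discretize(arr[mask], 25)$bins
  m <- frfx:::glcm_cpp(bins, c(6L, 3L, 3L), 2L)
  # axial direction (1,0,0): symmetrised matrix has all mass off-diagonal
  f <- frfx:::glcm_features_one(m[[1]], 2L)
  names(f) <- frfx:::GLCM_NAMES
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_joint_entropy"]), 1)
  expect_equal(unname(f["glcm_maximum_probability"]), 0.5)
  # oracle comparison for the same direction
  P <- oracle_glcm_matrix(bins, c(1, 0, 0))
  of <- oracle_glcm_features(P, 2)
  expect_equal(unname(f["glcm_correlation"]), unname(of["correlation"]), tolerance = 1e-12)
})

test_that("degenerate single-level regions take the documented texture conventions", {
  r <- fixture_constant_region()
  tx <- texture_features(r$arr, r$mask, bin_width = 25)
  expect_equal(unname(tx["glcm_contrast"]), 0)
  expect_equal(unname(tx["glcm_correlation"]), 1)
  expect_equal(unname(tx["glcm_joint_energy"]), 1)
  expect_equal(unname(tx["glcm_inverse_variance"]), 0)
  expect_equal(unname(tx["glszm_zone_percentage"]), 1 / 216) # one zone
  expect_equal(unname(tx["ngtdm_contrast"]), 0)
  expect_equal(unname(tx["ngtdm_busyness"]), 0)
  expect_false(any(is.na(tx)))
  # GLRLM long-run emphasis equals its closed form from oracle run counting
  runs <- list()
  for (d in oracle_directions()) {
    lens <- c()
    # brute-force: walk runs of the constant 6x6x6 cube along direction d
    seen <- array(FALSE, dim = c(6, 6, 6))
    for (z in 1:6) for (y in 1:6) for (x in 1:6) {
      p <- c(x, y, z) - d
      inside <- all(p >= 1 & p <= 6)
      if (inside) next # not a run start
      len <- 0; q <- c(x, y, z)
      while (all(q >= 1 & q <= 6)) { len <- len + 1; q <- q + d }
      lens <- c(lens, len)
    }
    runs[[length(runs) + 1]] <- sum(lens^2) / length(lens)
  }
  expect_equal(unname(tx["glrlm_long_run_emphasis"]), mean(unlist(runs)),
               tolerance = 1e-12)
})

test_that("texture features are invariant to direction order and intensity shifts", {
  r <- random_region(31)
  tx <- texture_features(r$arr, r$mask, bin_width = 10)
  # intensity shift: anchor at region minimum makes discretisation identical
  tx_shift <- texture_features(r$arr + 500, r$mask, bin_width = 10)
  expect_equal(tx, tx_shift, tolerance = 1e-12)
  fo <- first_order_features(r$arr[r$mask], bin_width = 10)
  fo_shift <- first_order_features(r$arr[r$mask] + 500, bin_width = 10)
  inv <- c("fo_entropy", "fo_uniformity", "fo_variance", "fo_sd", "fo_iqr",
           "fo_range", "fo_mad", "fo_rmad", "fo_skewness", "fo_kurtosis")
  expect_equal(fo[inv], fo_shift[inv], tolerance = 1e-9)
  expect_equal(unname(fo_shift["fo_mean"] - fo["fo_mean"]), 500, tolerance = 1e-9)
  expect_equal(unname(fo_shift["fo_median"] - fo["fo_median"]), 500, tolerance = 1e-9)
})

test_that("the catalogue contract holds: 106 named features, reproducibly", {
  cs <- fixture_case()
  am <- flr_analysis_mask(cs$post$seg, case_id = "case_x", timepoint = "post")
  v1 <- extract_catalogue(cs$post$image, am)
  expect_length(v1, 106)
  expect_identical(names(v1), catalogue_names())
  expect_false(any(is.na(v1)))
  v2 <- extract_catalogue(cs$post$image, am)
  expect_identical(v1, v2)
  # shipped manifest matches the in-code catalogue
  man <- jsonlite::read_json(system.file("extdata", "catalogue.json", package = "frfx"),
                             simplifyVector = TRUE)
  expect_identical(man$features, catalogue_names())
  expect_equal(sum(unlist(man$families)), 106)
})

test_that("catalogue vectors stay finite across random small regions", {
  for (s in 1:12) {
    r <- random_region(100 + s, side = 8)
    fo <- first_order_features(r$arr[r$mask])
    tx <- texture_features(r$arr, r$mask)
    expect_false(any(!is.finite(c(fo, tx))),
                 info = sprintf("non-finite feature at seed %d", 100 + s))
  }
})

test_that("the analysis mask removes vessels and tumour from the FLR", {
  obs <- array(0L, c(24, 24, 24))
  obs[2:21, 2:21, 2:21] <- 2L                  # 8000-voxel FLR
  seg0 <- seg_mask_set(obs, c(1, 1, 1))
  expect_equal(sum(flr_analysis_mask(seg0)$mask), 8000)
  obs[5:9, 5:9, 5:9] <- 3L                     # 125 vessel voxels inside
  seg1 <- seg_mask_set(obs, c(1, 1, 1))
  am <- flr_analysis_mask(seg1)
  expect_equal(sum(am$mask), 8000 - 125)
  expect_equal(am$n_voxels, 7875)
  # margin dilation removes a rim around the exclusions
  am1 <- flr_analysis_mask(seg1, dilate_margin = 1)
  expect_lt(sum(am1$mask), 7875)
  obs[obs == 2L] <- 4L                         # tumour covers all parenchyma
  expect_error(flr_analysis_mask(seg_mask_set(obs, c(1, 1, 1))), "no analysable")
})

test_that("standardisation fits on the training rows and drops constants", {
  set.seed(4)
  m <- cbind(a = rnorm(30), b = runif(30, 10, 20), c = rep(3, 30))
  expect_warning(st <- standardize(m, fit_rows = 1:20), "constant")
  expect_equal(unname(colMeans(st$z[1:20, ])), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(st$z[1:20, ], 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_equal(st$params$dropped, "c")
  # applying stored parameters equals manual (x - m) / s
  manual <- sweep(sweep(m[, c("a", "b")], 2, st$params$mean), 2, st$params$sd, "/")
  expect_equal(unname(apply_standardization(m, st$params)), unname(manual),
               tolerance = 1e-12)
  expect_error(standardize(cbind(k = rep(1, 10))), "constant")
})
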