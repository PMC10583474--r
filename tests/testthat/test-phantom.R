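test_that("liver geometry hits its volume and FLR-fraction targets", {
  seg <- make_liver_geometry(seed = 7L)
  vcc <- prod(c(2.5, 2.5, 2.5)) / 1000
  liver_all <- sum(seg$observed > 0)
  expect_gte(liver_all * vcc, 1330)
  expect_lte(liver_all * vcc, 1470)
  # FLR prefix is taken before vessels/tumour carve-outs; allow their share
  expect_gt(sum(seg$observed == 2) / liver_all, 0.3 - 0.05)
  expect_lt(sum(seg$observed == 2) / liver_all, 0.3 + 0.05)
})

test_that("geometry generation is deterministic and rejects bad targets", {
  a <- make_liver_geometry(seed = 3L)
  b <- make_liver_geometry(seed = 3L)
  expect_identical(a$observed, b$observed)
  expect_error(make_liver_geometry(target_flr_fraction = 0), "FLR required")
  expect_error(make_liver_geometry(target_tlv_cc = 4000), "infeasible")
  expect_error(make_liver_geometry(grid_shape = c(32, 32, 32), target_tlv_cc = 1400,
                                   spacing_mm = 2.5),
               "infeasible")
})

test_that("texture synthesis honours class means, the zero-noise limit and seeding", {
  obs <- array(0L, c(16, 16, 16))
  obs[4:13, 4:13, 4:13] <- 2L
  obs[4:13, 4:8, 4:13] <- 1L
  seg <- seg_mask_set(obs, c(2, 2, 2))
  tp0 <- default_tissue_params()
  for (nm in names(tp0)) tp0[[nm]]$sigma <- 0
  v0 <- synth_texture(seg, tp0, seed = 1L)
  expect_equal(unique(v0$voxels[obs == 2]), 105)
  expect_equal(unique(v0$voxels[obs == 1]), 105)
  expect_equal(unique(v0$voxels[obs == 0]), -75)

  v1 <- synth_texture(seg, seed = 5L)
  v2 <- synth_texture(seg, seed = 5L)
  expect_identical(v1$voxels, v2$voxels)
  expect_false(identical(v1$voxels, synth_texture(seg, seed = 6L)$voxels))

  bad <- default_tissue_params()
  bad$liver <- NULL
  expect_error(synth_texture(seg, bad, seed = 1L), "liver")
})

test_that("functional and oedema class means separate by the configured contrast", {
  cs <- fixture_case()
  cls <- frfx:::texture_class_map(cs$post$seg)
  v <- cs$post$image$voxels
  n_fx <- sum(cls == 3); n_oe <- sum(cls == 4)
  expect_gt(n_fx, 1e4)
  expect_gt(n_oe, 1e4)
  # 35 HU separation, tolerance covers correlated-field sampling noise
  expect_equal(mean(v[cls == 3]) - mean(v[cls == 4]), 35, tolerance = 0.1)
  expect_equal(mean(v[cls == 3]), 105, tolerance = 0.03)
})

test_that("PHLF outcome model follows its logistic closed form and direction", {
  g <- assign_phlf(25, seed = 1L)
  expect_equal(attr(g, "p_severe"), 0.5)
  expect_equal(attr(assign_phlf(50, seed = 1L), "p_severe"), 1 / (1 + exp(2)),
               tolerance = 1e-12)
  expect_lt(attr(assign_phlf(1e6, seed = 1L), "p_severe"), 1e-10)
  expect_error(assign_phlf(50, coeffs = list(a0 = 2, a1 = -0.1)), "invert")
  # strictly decreasing severe probability across the FRFxV grid
  ps <- vapply(c(10, 25, 40, 60), function(f) attr(assign_phlf(f, seed = 1L), "p_severe"),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # empirical monotonicity of drawn grades
  rate <- vapply(c(10, 25, 40, 60), function(f) {
    mean(vapply(1:400, function(s) phlf_severe(as.character(assign_phlf(f, seed = s))),
                logical(1)))
  }, numeric(1))
  expect_true(all(diff(rate) <= 0.02))
})

test_that("generated cases conserve truth volumes and respect theta", {
  cs <- fixture_case()
  vcc <- prod(cs$pre$seg$spacing) / 1000
  n_par <- sum(cs$post$seg$observed == 2)
  n_fx <- sum(cs$post$seg$truth == 1)
  n_oe <- sum(cs$post$seg$truth == 2)
  expect_equal(n_fx + n_oe, n_par)
  expect_equal(cs$truth_frl_cc, n_par * vcc)
  expect_equal(cs$truth_frfx_cc, n_fx * vcc)
  # frfx = (1 - theta) * frl within one voxel
  expect_lte(abs(cs$truth_frfx_cc - (1 - cs$truth_oedema_fraction) * cs$truth_frl_cc), vcc)
  # theta recovery from the truth mask
  expect_lte(abs(n_oe / n_par - cs$truth_oedema_fraction), 0.02)
  # post FLR at least as large as pre FLR
  expect_gte(sum(cs$post$seg$observed == 2), sum(cs$pre$seg$observed == 2) * 0.97)
  # pre-study FLR is entirely functional
  expect_true(all(cs$pre$seg$truth[cs$pre$seg$observed == 2] == 1))
})

test_that("theta = 0 cases have no oedema and degenerate inputs error", {
  sp <- default_sim_params("PVE"); sp$theta <- 0
  cs <- generate_case(sp, seed = 9L, images = "none")
  expect_equal(cs$truth_frfx_cc, cs$truth_frl_cc)
  expect_equal(sum(cs$post$seg$truth == 2), 0)
  sp$theta <- 1.4
  expect_error(generate_case(sp, seed = 9L), "theta")
  sp$theta <- 0.2; sp$growth <- -0.5
  expect_error(generate_case(sp, seed = 9L), "growth")
})

test_that("technique determines the elapsed-days window", {
  for (s in 1:6) {
    ca <- generate_case(default_sim_params("ALPPS"), seed = 20L + s, images = "none")
    expect_true(ca$meta$days_elapsed >= 7 && ca$meta$days_elapsed <= 22)
    cp <- generate_case(default_sim_params("PVE"), seed = 40L + s, images = "none")
    expect_true(cp$meta$days_elapsed >= 36 && cp$meta$days_elapsed <= 106)
  }
})

test_that("cohorts are reproducible, respect the split and calibrate PHLF counts", {
  co1 <- generate_cohort(n = 6, technique_split = c(3L, 3L), seed = 77L, images = "none")
  co2 <- generate_cohort(n = 6, technique_split = c(3L, 3L), seed = 77L, images = "none")
  expect_identical(co1$manifest, co2$manifest)
  expect_equal(as.vector(table(co1$manifest$technique)), c(3, 3))
  all_pve <- generate_cohort(n = 4, technique_split = c(0L, 4L), seed = 5L, images = "none")
  expect_true(all(all_pve$manifest$technique == "PVE"))
  expect_error(generate_cohort(n = 1, technique_split = c(1L, 0L)), "n must be")
  expect_error(generate_cohort(n = 6, technique_split = c(2L, 3L)), "sum to n")

  # mean severe-PHLF count per default 24-case cohort sits in the clinical band
  counts <- vapply(1:15, function(r) {
    co <- generate_cohort(seed = 1000L + r, images = "none")
    sum(phlf_severe(co$manifest$phlf_grade))
  }, numeric(1))
  expect_gte(mean(counts), 4)
  expect_lte(mean(counts), 9)
})
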