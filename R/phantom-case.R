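# Paired pre/post hepatic-modulation phantom cases with known functional /
# oedema composition and simulated PHLF outcomes.

#' Default outcome-model coefficients
#'
#' Severe post-hepatectomy liver failure (PHLF grade B or C) is drawn from a
#' logistic model that is strictly decreasing in the true functional remnant
#' volume percentage: P(PHLF >= B) = 1 / (1 + exp(-(a0 - a1 * FRFxV))). Severe
#' cases split C vs B with `p_grade_c_given_severe`; non-severe split A vs
#' none with `p_grade_a_given_mild`.
#'
#' @return Named list of coefficients.
#' @export
default_phlf_coeffs <- function() {
  list(a0 = 2.0, a1 = 0.08, p_grade_c_given_severe = 1 / 3, p_grade_a_given_mild = 0.22)
}

#' Simulate a PHLF grade from the true functional remnant percentage
#'
#' @param true_frfxv_pct true functional future liver remnant volume, percent
#'   of (TLV - TV).
#' @param coeffs coefficients, see [default_phlf_coeffs()]; `a1 < 0` is
#'   rejected because it would invert the direction of the outcome model
#'   (lower functional volume must mean higher failure risk).
#' @param seed integer seed.
#' @return A grade in `c("none", "A", "B", "C")`, with attribute `p_severe`.
#' @export
assign_phlf <- function(true_frfxv_pct, coeffs = default_phlf_coeffs(), seed = 1L) {
  if (coeffs$a1 < 0) stop_domain("a1 < 0 would invert the outcome direction")
  p <- plogis(coeffs$a0 - coeffs$a1 * true_frfxv_pct)
  grade <- with_seed(seed, {
    if (runif(1) < p) {
      if (runif(1) < coeffs$p_grade_c_given_severe) "C" else "B"
    } else {
      if (runif(1) < coeffs$p_grade_a_given_mild) "A" else "none"
    }
  })
  structure(grade, p_severe = p)
}

#' Default per-case simulation parameters
#'
#' The study conditions the generator emulates: remnant growth and oedema
#' burden differ by technique (ALPPS produces fast, oedema-rich growth over
#' days; PVE slower, cleaner growth over weeks). Oedema fraction theta is
#' Beta-distributed with mean 0.45 (ALPPS) / 0.20 (PVE) and concentration 10;
#' the growth multiplier g is Gamma(shape 8) with mean 1.2 / 0.7.
#'
#' @param technique `"ALPPS"` or `"PVE"`.
#' @param contrast oedema texture contrast multiplier, see
#'   [default_tissue_params()].
#' @return Named list of distribution parameters consumed by
#'   [generate_cohort()] / sampled into [generate_case()] inputs.
#' @export
default_sim_params <- function(technique = c("ALPPS", "PVE"), contrast = 1) {
  technique <- match.arg(technique)
  alpps <- technique == "ALPPS"
  list(technique = technique,
       grid_shape = c(64L, 64L, 64L), spacing_mm = c(2.5, 2.5, 2.5),
       tlv_mean = 1400, tlv_sd = 150, tlv_range = c(1100, 1650),
       flr_fraction_range = c(0.22, 0.40),
       theta_mean = if (alpps) 0.45 else 0.20, theta_conc = 10,
       growth_mean = if (alpps) 1.2 else 0.7, growth_shape = 8,
       tumour_range = c(30, 120), vessel_density = 0.03,
       days_range = if (alpps) c(7L, 22L) else c(36L, 106L),
       tissue_params = default_tissue_params(contrast),
       phlf_coeffs = default_phlf_coeffs())
}

rtrunc <- function(rfun, lo, hi, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    x <- rfun()
    if (x >= lo && x <= hi) return(x)
  }
  min(max(x, lo), hi)
}

# grow the FLR blob to `target_n` voxels by chamfer distance, never into the
# non-FLR liver or tumour
grow_flr <- function(flr, liver, tumour, target_n) {
  if (target_n <= sum(flr)) return(flr)
  d <- chamfer_dist_cpp(as.logical(flr), dim(flr))
  cand <- which(!flr & !(liver & !flr) & !tumour)
  need <- target_n - sum(flr)
  if (length(cand) < need)
    stop_domain("geometry infeasible: not enough room to grow the FLR")
  ord <- cand[order(d[cand] * (length(d) + 1) + cand)[seq_len(need)]]
  grown <- flr
  grown[ord] <- TRUE
  grown
}

# oedema = outer rim of the grown FLR blob: the theta-quantile of erosion
# depth, exact to one voxel, ties broken by linear index
oedema_rim <- function(blob, parenchyma, theta) {
  n_par <- sum(parenchyma)
  k <- round(theta * n_par)
  oed <- logical(length(blob)); dim(oed) <- dim(blob)
  if (k > 0) {
    depth <- chamfer_dist_cpp(as.logical(!blob), dim(blob))
    pv <- which(parenchyma)
    oed[pv[order(depth[pv] * (length(depth) + 1) + pv)[seq_len(k)]]] <- TRUE
  }
  oed
}

#' Generate one paired pre/post phantom case
#'
#' Builds the pre-modulation geometry, grows the FLR by the multiplier `g`
#' (post FLR volume = pre FLR volume x (1 + g)), deposits an oedema rim
#' occupying fraction `theta` of the post-FLR parenchyma, synthesises CT-like
#' textures, samples patient metadata and draws the PHLF grade from the
#' outcome model.
#'
#' @param sim_params list as from [default_sim_params()], plus fixed per-case
#'   values `theta` (oedema fraction in `[0, 1]`), `growth` (g >= 0),
#'   `flr_fraction`, `tlv_cc`, `tumour_cc`. Missing fixed values are sampled
#'   from the distribution fields.
#' @param seed integer seed.
#' @param images which intensity volumes to synthesise: `"both"`, `"post"`
#'   (volumetry-plus-classification studies need only the post image) or
#'   `"none"` (mask-only studies).
#' @return An object of class `phantom_case`.
#' @export
generate_case <- function(sim_params = default_sim_params(), seed = 1L,
                          images = c("both", "post", "none")) {
  images <- match.arg(images)
  sp <- sim_params
  draws <- with_seed(derive_seed(seed, 0L, 3L), {
    list(
      tlv = sp[["tlv_cc"]] %||% rtrunc(function() rnorm(1, sp$tlv_mean, sp$tlv_sd),
                                       sp$tlv_range[1], sp$tlv_range[2]),
      flr_fraction = sp[["flr_fraction"]] %||%
        runif(1, sp$flr_fraction_range[1], sp$flr_fraction_range[2]),
      theta = sp[["theta"]] %||% rbeta(1, sp$theta_mean * sp$theta_conc,
                                       (1 - sp$theta_mean) * sp$theta_conc),
      growth = sp[["growth"]] %||% rgamma(1, shape = sp$growth_shape,
                                          rate = sp$growth_shape / sp$growth_mean),
      tumour_cc = sp[["tumour_cc"]] %||% runif(1, sp$tumour_range[1], sp$tumour_range[2]),
      height = rtrunc(function() rnorm(1, 170, 10), 120, 220),
      weight = rtrunc(function() rnorm(1, 75, 12), 30, 200),
      days = sample(seq(sp$days_range[1], sp$days_range[2]), 1)
    )
  })
  if (draws$theta < 0 || draws$theta > 1) stop_domain("theta must lie in [0, 1]")
  if (draws$growth < 0) stop_domain("growth multiplier g must be >= 0")

  core <- liver_geometry_core(sp$grid_shape, sp$spacing_mm, draws$tlv,
                              draws$flr_fraction, draws$tumour_cc,
                              derive_seed(seed, 1L, 3L))
  vcc <- voxel_cc(core$spacing)

  # pre study: FLR entirely functional
  vess_pre <- lay_vessels(core$liver, core$tumour, core$spacing, sp$vessel_density,
                          derive_seed(seed, 2L, 3L))
  obs_pre <- assemble_observed(core$liver, core$flr, vess_pre, core$tumour, core$grid_shape)
  truth_pre <- array(TRUTH_LABELS[["na"]], dim = core$grid_shape)
  truth_pre[obs_pre == SEG_LABELS[["flr"]]] <- TRUTH_LABELS[["functional"]]
  seg_pre <- seg_mask_set(obs_pre, core$spacing, truth_pre)

  # post study: grown FLR with an oedema rim; non-FLR side unchanged
  target_n <- round(sum(core$flr) * (1 + draws$growth))
  blob <- grow_flr(core$flr, core$liver, core$tumour, target_n)
  liver_post <- (core$liver & !core$flr) | blob
  vess_post <- lay_vessels(liver_post, core$tumour, core$spacing, sp$vessel_density,
                           derive_seed(seed, 3L, 3L))
  parench <- blob & !vess_post
  oed <- oedema_rim(blob, parench, draws$theta)
  obs_post <- assemble_observed(liver_post, blob, vess_post, core$tumour, core$grid_shape)
  truth_post <- array(TRUTH_LABELS[["na"]], dim = core$grid_shape)
  truth_post[obs_post == SEG_LABELS[["flr"]]] <- TRUTH_LABELS[["functional"]]
  truth_post[oed & obs_post == SEG_LABELS[["flr"]]] <- TRUTH_LABELS[["oedema"]]
  seg_post <- seg_mask_set(obs_post, core$spacing, truth_post)

  n_par <- sum(obs_post == SEG_LABELS[["flr"]])
  n_oed <- sum(truth_post == TRUTH_LABELS[["oedema"]])
  truth_frl_cc <- n_par * vcc
  truth_frfx_cc <- (n_par - n_oed) * vcc

  tlv_cc <- sum(core$liver) * vcc
  tv_cc <- sum(core$tumour) * vcc
  true_frfxv_pct <- truth_frfx_cc / (tlv_cc - tv_cc) * 100
  grade <- assign_phlf(true_frfxv_pct, sp$phlf_coeffs, derive_seed(seed, 4L, 3L))

  img_pre <- if (images == "both")
    synth_texture(seg_pre, sp$tissue_params, derive_seed(seed, 5L, 3L)) else NULL
  img_post <- if (images %in% c("both", "post"))
    synth_texture(seg_post, sp$tissue_params, derive_seed(seed, 6L, 3L)) else NULL

  meta <- patient_meta(case_id = sprintf("case_%08d", as.integer(seed) %% 1e8),
                       height_cm = draws$height, weight_kg = draws$weight,
                       technique = sp$technique, days_elapsed = draws$days,
                       phlf_grade = as.character(grade))
  structure(list(meta = meta,
                 pre = list(image = img_pre, seg = seg_pre),
                 post = list(image = img_post, seg = seg_post),
                 truth_oedema_fraction = draws$theta,
                 truth_frl_cc = truth_frl_cc, truth_frfx_cc = truth_frfx_cc,
                 true_frfxv_pct = true_frfxv_pct,
                 tlv_cc = tlv_cc, tv_cc = tv_cc,
                 growth = draws$growth, p_severe = attr(grade, "p_severe")),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s (%s): FRL %0.f cc, FRFx %.0f cc (theta %.2f), PHLF %s\n",
              x$meta$case_id, x$meta$technique, x$truth_frl_cc, x$truth_frfx_cc,
              x$truth_oedema_fraction, x$meta$phlf_grade))
  invisible(x)
}

#' Generate a synthetic cohort of phantom cases
#'
#' Per-case seeds are derived deterministically from the master seed, so the
#' cohort is reproducible and unchanged by reordering.
#'
#' @param n number of cases (>= 2); default 24.
#' @param technique_split integer length-2 `c(ALPPS, PVE)` summing to `n`;
#'   default `c(11, 13)`.
#' @param sim_params_dist list of two [default_sim_params()]-style lists named
#'   `ALPPS` and `PVE`.
#' @param seed master integer seed.
#' @param images passed to [generate_case()].
#' @return List with `cases` (list of `phantom_case`) and `manifest`
#'   (data.frame of metadata and truth values, one row per case).
#' @export
generate_cohort <- function(n = 24L, technique_split = c(11L, 13L),
                            sim_params_dist = list(ALPPS = default_sim_params("ALPPS"),
                                                   PVE = default_sim_params("PVE")),
                            seed = 1L, images = c("both", "post", "none")) {
  images <- match.arg(images)
  if (!is_count(n) || n < 2) stop_domain("n must be an integer >= 2")
  if (sum(technique_split) != n) stop_domain("technique_split must sum to n")
  techs <- rep(c("ALPPS", "PVE"), times = technique_split)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- sim_params_dist[[techs[i]]]
    cases[[i]] <- generate_case(sp, derive_seed(seed, i, 10L), images = images)
    cases[[i]]$meta$case_id <- sprintf("case_%03d", i)
  }
  manifest <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(case_id = cs$meta$case_id, technique = cs$meta$technique,
               height_cm = cs$meta$height_cm, weight_kg = cs$meta$weight_kg,
               days_elapsed = cs$meta$days_elapsed, phlf_grade = cs$meta$phlf_grade,
               theta = cs$truth_oedema_fraction,
               truth_frl_cc = cs$truth_frl_cc, truth_frfx_cc = cs$truth_frfx_cc,
               stringsAsFactors = FALSE)
  }))
  list(cases = cases, manifest = manifest)
}
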