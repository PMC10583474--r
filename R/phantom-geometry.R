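# Synthetic liver geometry. The liver is an axis-aligned ellipsoid-like blob,
# the FLR is one side of a plane through it, the tumour a sphere buried in the
# non-FLR side, vessels random cylinders. All draws are pure functions of the
# seed. Voxel centres sit at (i - 0.5) * spacing mm.

liver_geometry_core <- function(grid_shape, spacing_mm, target_tlv_cc,
                                target_flr_fraction, tumour_cc, seed) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop_domain("grid_shape must be 3 integers >= 8")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop_domain("spacing must be positive")
  if (target_flr_fraction <= 0 || target_flr_fraction >= 1)
    stop_domain("FLR required: target_flr_fraction must lie in (0, 1)")
  grid_cc <- prod(grid_shape * spacing_mm) / 1000
  if (target_tlv_cc <= 0 || target_tlv_cc > 0.6 * grid_cc)
    stop_domain("geometry infeasible: target_tlv_cc exceeds 60%% of grid volume (%.0f cc)",
                0.6 * grid_cc)

  with_seed(seed, {
    ext <- grid_shape * spacing_mm
    # semi-axes: a along x, ratios r2 (y), r3 (z); rescaled toward a sphere if
    # the sampled shape would not fit the grid with a 2-voxel margin
    abc <- target_tlv_cc * 1000 * 3 / (4 * pi) # product of semi-axes, mm^3
    r2 <- runif(1, 0.88, 1)
    r3 <- runif(1, 0.88, 1)
    amax <- min(ext) / 2 - 2 * max(spacing_mm)
    a <- (abc / (r2 * r3))^(1 / 3)
    if (a > amax) {
      a <- amax
      rr <- abc / a^3
      if (rr > 1) stop_domain("geometry infeasible: liver of %.0f cc does not fit the grid",
                              target_tlv_cc)
      r2 <- r3 <- sqrt(rr)
    }
    semi <- c(a, r2 * a, r3 * a)
    centre <- ext / 2 + runif(3, -1, 1) * spacing_mm
    if (any(centre - semi < spacing_mm) || any(centre + semi > ext - spacing_mm))
      stop_domain("geometry infeasible: liver of %.0f cc does not fit the grid", target_tlv_cc)

    cx <- ((seq_len(grid_shape[1]) - 0.5) * spacing_mm[1] - centre[1]) / semi[1]
    cy <- ((seq_len(grid_shape[2]) - 0.5) * spacing_mm[2] - centre[2]) / semi[2]
    cz <- ((seq_len(grid_shape[3]) - 0.5) * spacing_mm[3] - centre[3]) / semi[3]
    q <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
    liver <- q <= 1
    n_liver <- sum(liver)
    if (abs(n_liver * voxel_cc(spacing_mm) - target_tlv_cc) > 0.05 * target_tlv_cc)
      stop_domain("geometry infeasible: digitised liver volume misses the target by > 5%%")

    # FLR = prefix of liver voxels in (x, y, z) lexicographic order: one side
    # of the plane x = cut plus a partial slab, so the requested fraction is
    # met to one voxel while staying connected.
    li <- which(liver)
    co <- arrayInd(li, grid_shape)
    ord <- order((co[, 1] * grid_shape[2] + co[, 2]) * grid_shape[3] + co[, 3])
    k <- round(target_flr_fraction * n_liver)
    k <- max(1L, min(n_liver - 1L, k))
    flr <- logical(length(liver)); dim(flr) <- grid_shape
    flr[li[ord[seq_len(k)]]] <- TRUE

    tumour <- logical(length(liver)); dim(tumour) <- grid_shape
    if (tumour_cc > 0) {
      # deepest point of the non-FLR side, by chamfer depth from the liver hull
      depth <- chamfer_dist_cpp(as.logical(!liver), dim(liver)) * min(spacing_mm) / 3
      cand <- which(liver & !flr)
      ctr <- cand[which.max(depth[cand])]
      r_t <- (tumour_cc * 1000 * 3 / (4 * pi))^(1 / 3)
      if (depth[ctr] < r_t)
        stop_domain("geometry infeasible: tumour of %.0f cc does not fit the non-FLR side",
                    tumour_cc)
      cc3 <- arrayInd(ctr, grid_shape)
      px <- ((seq_len(grid_shape[1]) - 0.5) * spacing_mm[1] - (cc3[1] - 0.5) * spacing_mm[1])^2
      py <- ((seq_len(grid_shape[2]) - 0.5) * spacing_mm[2] - (cc3[2] - 0.5) * spacing_mm[2])^2
      pz <- ((seq_len(grid_shape[3]) - 0.5) * spacing_mm[3] - (cc3[3] - 0.5) * spacing_mm[3])^2
      d2 <- outer(outer(px, py, "+"), pz, "+")
      tumour <- d2 <= r_t^2 & liver & !flr
    }
    list(liver = liver, flr = flr, tumour = tumour,
         grid_shape = grid_shape, spacing = spacing_mm)
  })
}

# Random vessel cylinders inside `region` (excluding tumour) until roughly
# `density` of the region volume is covered.
lay_vessels <- function(region, tumour, spacing, density, seed) {
  vess <- logical(length(region)); dim(vess) <- dim(region)
  if (density <= 0) return(vess)
  target <- round(density * sum(region))
  idx <- which(region & !tumour)
  if (length(idx) < 2L) return(vess)
  gs <- dim(region)
  allowed <- region & !tumour
  with_seed(seed, {
    covered <- 0L
    for (attempt in seq_len(300)) {
      if (covered >= target) break
      ab <- idx[sample.int(length(idx), 2L)]
      A <- (as.numeric(arrayInd(ab[1], gs)) - 0.5) * spacing
      B <- (as.numeric(arrayInd(ab[2], gs)) - 0.5) * spacing
      r <- runif(1, 1.0, 2.2)
      covered <- covered + add_cylinder_cpp(vess, allowed, gs, spacing, A, B, r)
    }
  })
  vess
}

#' Generate a synthetic liver segmentation
#'
#' Builds a connected ellipsoid-like liver of approximately `target_tlv_cc`,
#' carves out a future liver remnant (FLR) as one side of a plane through the
#' liver holding `target_flr_fraction` of its volume (to one voxel), buries a
#' spherical tumour in the non-FLR side and threads random cylindrical vessels
#' through the parenchyma. Identical inputs give bit-identical masks.
#'
#' @param grid_shape integer length-3 grid dimensions (default 64^3).
#' @param spacing_mm voxel spacing in mm (default 2.5 isotropic).
#' @param target_tlv_cc target total liver volume in cc; must be achievable
#'   within the grid (at most 60% of the grid's physical volume).
#' @param target_flr_fraction FLR share of the liver volume, in (0, 1).
#' @param tumour_cc tumour volume in cc (0 disables the tumour).
#' @param vessel_density approximate fraction of liver volume covered by
#'   vessels.
#' @param seed integer seed.
#' @return A [seg_mask_set] with observed labels and no truth grid.
#' @export
make_liver_geometry <- function(grid_shape = c(64L, 64L, 64L), spacing_mm = c(2.5, 2.5, 2.5),
                                target_tlv_cc = 1400, target_flr_fraction = 0.3,
                                tumour_cc = 80, vessel_density = 0.03, seed = 1L) {
  if (!is_count(seed)) stop_domain("seed must be an integer")
  core <- liver_geometry_core(grid_shape, spacing_mm, target_tlv_cc,
                              target_flr_fraction, tumour_cc, seed)
  vess <- lay_vessels(core$liver, core$tumour, core$spacing, vessel_density,
                      derive_seed(seed, 0L, 1L))
  observed <- assemble_observed(core$liver, core$flr, vess, core$tumour, core$grid_shape)
  seg_mask_set(observed, core$spacing)
}

assemble_observed <- function(liver, flr, vessels, tumour, grid_shape) {
  observed <- array(SEG_LABELS[["background"]], dim = grid_shape)
  observed[liver] <- SEG_LABELS[["liver"]]
  observed[flr] <- SEG_LABELS[["flr"]]
  observed[vessels] <- SEG_LABELS[["vessel"]]
  observed[tumour] <- SEG_LABELS[["tumour"]]
  observed
}
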