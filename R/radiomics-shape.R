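# 3-D shape features: mesh-based volume/surface via a marching-tetrahedra
# triangulation of the binary mask, diameters from surface voxels, axis
# features from the eigen-decomposition of the voxel-coordinate covariance.

SHAPE_NAMES <- c("sh_mesh_volume", "sh_voxel_volume", "sh_surface_area",
                 "sh_surface_volume_ratio", "sh_sphericity", "sh_compactness1",
                 "sh_compactness2", "sh_max_3d_diameter",
                 "sh_max_2d_diameter_slice", "sh_max_2d_diameter_column",
                 "sh_max_2d_diameter_row", "sh_major_axis_length",
                 "sh_minor_axis_length", "sh_least_axis_length",
                 "sh_elongation", "sh_flatness")

# voxels of `mask` with at least one 6-neighbour outside the mask (or grid)
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <- m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1)) interior <- interior & shift_and(mask, ax, by)
  mask & !interior
}

max_2d_diameter <- function(coords_mm, slice_index) {
  best <- 0
  for (s in unique(slice_index)) {
    pts <- coords_mm[slice_index == s, , drop = FALSE]
    if (nrow(pts) < 2) next
    d <- max_pairwise_dist_cpp(cbind(pts, 0))
    if (d > best) best <- d
  }
  best
}

#' Shape features of a 3-D mask
#'
#' @param mask logical 3-D array, non-empty. A single-voxel mask yields
#'   degenerate mesh/axis features: they are returned with a warning and the
#'   attribute `degenerate = TRUE`.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return Named numeric vector of length 16 (volumes mm^3, areas mm^2,
#'   lengths mm; sphericity/compactness/elongation/flatness dimensionless).
#' @export
shape_features <- function(mask, spacing) {
  if (!any(mask)) stop_domain("empty mask")
  spacing <- rep_len(as.numeric(spacing), 3L)
  n <- sum(mask)
  degenerate <- n == 1L
  # anti-aliased surface: mesh the 0.5 level-set of the Gaussian-smoothed
  # indicator (sigma = 1 voxel); small masks whose smoothed field never
  # crosses the level fall back to the binary indicator
  k <- gaussian_kernel_1d(1.0)
  field <- sep_conv3_cpp(as.numeric(mask), as.integer(dim(mask)), k)
  if (max(field) <= 0.5) field <- as.numeric(mask)
  mesh <- mesh_area_volume_cpp(field, as.integer(dim(mask)), spacing, 0.5)
  A <- mesh$area
  V <- mesh$volume
  vox_vol <- n * prod(spacing)

  sv <- surface_voxels(mask)
  si <- arrayInd(which(sv), dim(mask))
  coords <- sweep(si - 0.5, 2, spacing, "*")
  max3d <- if (nrow(coords) >= 2) max_pairwise_dist_cpp(coords) else 0
  d_slice <- max_2d_diameter(coords[, 1:2, drop = FALSE], si[, 3])   # in-plane (x,y) per z
  d_col <- max_2d_diameter(coords[, c(1, 3), drop = FALSE], si[, 2]) # (x,z) per y
  d_row <- max_2d_diameter(coords[, 2:3, drop = FALSE], si[, 1])     # (y,z) per x

  ai <- arrayInd(which(mask), dim(mask))
  pc <- sweep(ai - 0.5, 2, spacing, "*")
  if (n >= 2) {
    ev <- sort(pmax(eigen(stats::cov(pc), symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  out <- c(V, vox_vol, A,
           if (V > 0) A / V else Inf,
           if (A > 0) (36 * pi * V^2)^(1 / 3) / A else 0,
           if (A > 0) V / (sqrt(pi) * A^1.5) else 0,
           if (A > 0) 36 * pi * V^2 / A^3 else 0,
           max3d, d_slice, d_col, d_row,
           axes[1], axes[2], axes[3], elong, flat)
  names(out) <- SHAPE_NAMES
  if (degenerate) {
    warning("single-voxel mask: mesh and axis shape features are degenerate")
    attr(out, "degenerate") <- TRUE
  }
  out
}
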