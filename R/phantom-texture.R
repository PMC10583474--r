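# Correlated Gaussian random-field texture synthesis. Each tissue class gets
# intensity mu + sigma * G, where G is white noise smoothed by a separable
# Gaussian of scale lambda (voxels) and renormalised to unit variance. Classes
# sharing a lambda share the underlying field, which keeps texture continuous
# across the boundary between, say, functional FLR and the rest of the liver.

#' Default tissue texture parameters
#'
#' Contrast-CT-plausible means with separable but overlapping distributions:
#' functional parenchyma is brighter and finer-grained than oedema/congestion,
#' vessels are bright and thin, tumour hypodense. `mu`/`sigma` in HU, `lambda`
#' (correlation length) in voxels.
#'
#' @param contrast multiplier on the oedema-vs-functional mean difference;
#'   `contrast = 0` makes oedema statistically identical to functional tissue
#'   (null phantoms).
#' @return Named list of per-class `list(mu, sigma, lambda)`.
#' @export
default_tissue_params <- function(contrast = 1) {
  fx <- list(mu = 105, sigma = 12, lambda = 1.0)
  oe <- list(mu = 105 - 35 * contrast, sigma = if (contrast > 0) 20 else 12,
             lambda = if (contrast > 0) 2.0 else 1.0)
  list(background = list(mu = -75, sigma = 10, lambda = 0),
       liver = fx, functional = fx, oedema = oe,
       vessel = list(mu = 180, sigma = 10, lambda = 0.5),
       tumour = list(mu = 45, sigma = 15, lambda = 1.5))
}

TEXTURE_CLASSES <- c("background", "liver", "functional", "oedema", "vessel", "tumour")

# map observed + truth grids to integer texture class codes (TEXTURE_CLASSES)
texture_class_map <- function(seg) {
  obs <- seg$observed
  # observed labels 0..4 -> class codes
  lut <- c(1L, 2L, 3L, 5L, 6L) # background, liver, flr->functional, vessel, tumour
  cls <- array(lut[obs + 1L], dim = dim(obs))
  if (!is.null(seg$truth))
    cls[obs == SEG_LABELS[["flr"]] & seg$truth == TRUTH_LABELS[["oedema"]]] <- 4L
  cls
}

gaussian_kernel_1d <- function(lambda) {
  if (lambda <= 0) return(1)
  r <- max(1L, ceiling(3 * lambda))
  k <- exp(-((-r:r)^2) / (2 * lambda^2))
  k / sum(k)
}

# unit-variance correlated field: white noise convolved with the kernel along
# each axis, then divided by the theoretical standard deviation of the
# convolution (exact away from the zero-padded borders)
unit_field <- function(grid_shape, lambda, seed) {
  with_seed(seed, {
    w <- array(rnorm(prod(grid_shape)), dim = grid_shape)
    if (lambda <= 0) return(w)
    k <- gaussian_kernel_1d(lambda)
    f <- sep_conv3_cpp(as.numeric(w), as.integer(grid_shape), k)
    dim(f) <- grid_shape
    f / sqrt(sum(k^2)^3)
  })
}

# bounding box (with margin) of a set of linear indices
index_bbox <- function(idx, grid_shape, margin) {
  ai <- arrayInd(idx, grid_shape)
  lo <- pmax(1L, apply(ai, 2, min) - margin)
  hi <- pmin(grid_shape, apply(ai, 2, max) + margin)
  list(lo = lo, hi = hi, dims = hi - lo + 1L)
}

#' Synthesise a CT-like intensity volume over a segmentation
#'
#' @param mask_set a [seg_mask_set]; truth labels, when present, split the FLR
#'   into functional and oedema texture classes.
#' @param tissue_params named list of `list(mu, sigma, lambda)` per class, as
#'   produced by [default_tissue_params()]; every class present in the masks
#'   must have an entry.
#' @param seed integer seed; identical seeds give identical volumes.
#' @return An [image_volume].
#' @export
synth_texture <- function(mask_set, tissue_params = default_tissue_params(), seed = 1L) {
  stopifnot(inherits(mask_set, "seg_mask_set"))
  cls <- texture_class_map(mask_set)
  codes <- sort(unique(as.vector(cls)))
  present <- TEXTURE_CLASSES[codes]
  missing <- setdiff(present, names(tissue_params))
  if (length(missing))
    stop_domain("missing tissue params for label(s): %s", paste(missing, collapse = ", "))
  for (p in present) {
    tp <- tissue_params[[p]]
    if (tp$sigma < 0 || tp$lambda < 0)
      stop_domain("sigma and lambda must be >= 0 (class %s)", p)
  }
  gs <- dim(mask_set$observed)
  vox <- array(0, dim = gs)
  # classes sharing a correlation length share one field, synthesised over the
  # bounding box of their union (padded by the kernel radius)
  lam <- vapply(tissue_params[present], `[[`, numeric(1), "lambda")
  sig <- vapply(tissue_params[present], `[[`, numeric(1), "sigma")
  lambdas <- sort(unique(lam[sig > 0]))
  for (i in seq_along(lambdas)) {
    lv <- lambdas[i]
    member_codes <- codes[sig > 0 & lam == lv]
    idx <- which(cls %in% member_codes)
    if (!length(idx)) next
    if (lv <= 0) {
      g <- with_seed(derive_seed(seed, i, 2L), rnorm(length(idx)))
      sub_codes <- cls[idx]
      for (ci in member_codes) {
        p <- TEXTURE_CLASSES[ci]
        sel <- sub_codes == ci
        vox[idx[sel]] <- tissue_params[[p]]$mu + tissue_params[[p]]$sigma * g[sel]
      }
    } else {
      bb <- index_bbox(idx, gs, margin = length(gaussian_kernel_1d(lv)) %/% 2)
      f <- unit_field(bb$dims, lv, derive_seed(seed, i, 2L))
      sub_cls <- cls[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
      block <- vox[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
      for (ci in member_codes) {
        p <- TEXTURE_CLASSES[ci]
        m <- sub_cls == ci
        block[m] <- tissue_params[[p]]$mu + tissue_params[[p]]$sigma * f[m]
      }
      vox[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- block
    }
  }
  for (ci in codes[sig == 0]) vox[cls == ci] <- tissue_params[[TEXTURE_CLASSES[ci]]]$mu
  image_volume(vox, mask_set$spacing)
}
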