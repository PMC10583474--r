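# Patch-level functional-tissue classification. The spatial unit is a
# non-overlapping cubic patch (default 4^3 voxels = 1.0 cc at 2.5 mm): large
# enough for stable first-order statistics, small enough to localise oedema.
# Training patches come from phantom truth masks (pre-study FLR and
# truth-functional post regions = functional; truth-oedema regions = oedema);
# only the first-order family enters selection and the logistic model.

#' Default classifier configuration
#'
#' @return List: `patch_size` (voxels per edge), `top_k` selected features,
#'   `bin_width` (HU), `l2_strength`, `n_bins_ig`, `purity` (minimum truth
#'   fraction for a labelled training patch), `coverage` (minimum in-mask
#'   fraction for a classifiable patch), `threshold` (probability cut),
#'   `seed`.
#' @export
default_classifier_config <- function() {
  list(patch_size = 4L, top_k = 5L, bin_width = 25, l2_strength = 1,
       n_bins_ig = 10, purity = 0.9, coverage = 0.5, threshold = 0.5,
       seed = 1L)
}

# first-order features + voxel counts of every patch intersecting the mask
patch_first_order <- function(vox, mask, spacing, patch_size, bin_width) {
  idx <- which(mask)
  if (length(idx) == 0) stop_domain("empty analysis mask")
  ai <- arrayInd(idx, dim(mask))
  pgrid <- as.integer(ceiling(dim(mask) / patch_size))
  pc <- (ai - 1L) %/% as.integer(patch_size)
  pid <- pc[, 1] + pgrid[1] * (pc[, 2] + pgrid[2] * pc[, 3]) + 1L
  f <- factor(pid)
  g <- as.integer(f)
  feats <- first_order_grouped(vox[idx], g, bin_width, prod(spacing))
  list(features = feats, patch_id = as.integer(levels(f)),
       count = tabulate(g, nbins = max(g)), pgrid = pgrid,
       group = g, voxel_index = idx)
}

# truth composition per patch (fraction of in-mask voxels that are oedema)
patch_truth_fraction <- function(truth, voxel_index, group) {
  oed <- as.numeric(truth[voxel_index] == TRUTH_LABELS[["oedema"]])
  rowsum(oed, group)[, 1] / tabulate(group, nbins = max(group))
}

# Patch-level candidate features: the intensive first-order members. Energy
# and total energy are extensive (they scale with in-mask voxel count), so on
# variable-coverage patches they measure patch geometry — how much of a cube
# lies inside the parenchyma — rather than tissue texture; they remain in the
# whole-region catalogue but never enter patch selection.
patch_candidate_features <- function() setdiff(FO_NAMES, c("fo_energy", "fo_total_energy"))

harvest_case_patches <- function(case, timepoint, config) {
  side <- case[[timepoint]]
  if (is.null(side$image))
    stop_domain("case %s has no %s image volume", case$meta$case_id, timepoint)
  am <- flr_analysis_mask(side$seg, case_id = case$meta$case_id, timepoint = timepoint)
  pf <- patch_first_order(side$image$voxels, am$mask, side$image$spacing,
                          config$patch_size, config$bin_width)
  keep <- pf$count / config$patch_size^3 >= config$coverage
  frac_oed <- patch_truth_fraction(side$seg$truth, pf$voxel_index, pf$group)
  label <- ifelse(frac_oed >= config$purity, "oedema",
                  ifelse(frac_oed <= 1 - config$purity, "functional", NA))
  list(features = pf$features[keep, , drop = FALSE], label = label[keep],
       case_id = case$meta$case_id, timepoint = timepoint)
}

#' Train the functional-tissue patch classifier
#'
#' Harvests labelled patches from a training cohort with truth masks,
#' standardises the first-order feature matrix, ranks features by information
#' gain (ties broken lexicographically by name), reports pooled-variance t
#' screening, fits an L2-penalised logistic regression on the top-k features
#' and runs an exploratory k-means (k = 2) subgrouping reported as a Rand
#' index against the truth labels.
#'
#' @param cases list of `phantom_case` objects with truth masks and images.
#' @param config see [default_classifier_config()].
#' @return List with `selection` (a data.frame selection report), `model`
#'   (a `logistic_model` carrying the standardisation parameters) and
#'   `kmeans_rand_index`.
#' @export
train_functional_classifier <- function(cases, config = default_classifier_config()) {
  config <- utils::modifyList(default_classifier_config(), config)
  harvested <- list()
  for (cs in cases) {
    harvested[[length(harvested) + 1]] <- harvest_case_patches(cs, "pre", config)
    harvested[[length(harvested) + 1]] <- harvest_case_patches(cs, "post", config)
  }
  feats <- do.call(rbind, lapply(harvested, `[[`, "features"))
  labels <- unlist(lapply(harvested, `[[`, "label"))
  ok <- !is.na(labels)
  feats <- feats[ok, , drop = FALSE]
  labels <- labels[ok]
  tab <- table(labels)
  if (length(tab) < 2 || min(tab) < 10)
    stop_domain("need >= 10 training patches per class (got %s)",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))

  std <- standardize(feats)
  z <- std$z
  ig <- vapply(colnames(z), function(f)
    information_gain(z[, f], labels, n_bins = config$n_bins_ig), numeric(1))
  tt <- screen_ttest(z, labels)
  candidates <- intersect(colnames(z), patch_candidate_features())
  ord <- order(-ig[candidates], candidates)
  ranked <- candidates[ord]
  chosen <- head(ranked, config$top_k)
  selection <- data.frame(feature = colnames(z), info_gain = unname(ig),
                          t = tt$t, p = tt$p,
                          rank = match(colnames(z), ranked),
                          candidate = colnames(z) %in% candidates,
                          selected = colnames(z) %in% chosen,
                          stringsAsFactors = FALSE)
  selection <- selection[order(selection$rank, selection$feature), ]
  rownames(selection) <- NULL

  model <- fit_logistic(z[, chosen, drop = FALSE],
                        labels == "functional",
                        l2_strength = config$l2_strength, seed = config$seed)
  model$standardization <- std$params[c("mean", "sd", "kept")]
  model$standardization$mean <- std$params$mean[chosen]
  model$standardization$sd <- std$params$sd[chosen]
  model$standardization$kept <- chosen
  model$threshold <- config$threshold
  model$patch_size <- config$patch_size
  model$bin_width <- config$bin_width

  km <- kmeans_profiles(z, k = 2, seed = config$seed)
  list(selection = selection, model = model,
       kmeans_rand_index = rand_index(km$assignments, as.integer(factor(labels))))
}

#' Classify the patches of a post-modulation analysis mask
#'
#' Tiles the analysis mask into congruent cubic patches; patches covering at
#' least the coverage fraction are classified by the logistic model, and the
#' parenchyma of low-coverage patches inherits the label of the nearest
#' classified patch. The functional remnant volume is the total parenchyma
#' volume assigned a functional label.
#'
#' @param volume an [image_volume].
#' @param analysis_mask an [flr_analysis_mask()] result.
#' @param model trained `logistic_model` from [train_functional_classifier()].
#' @param patch_size cube edge in voxels (defaults to the model's).
#' @param coverage minimum in-mask fraction for direct classification.
#' @return Object of class `functional_map`: list with the per-patch
#'   probability array `prob` (NA outside classified patches), `patch_size`,
#'   `frfx_cc`, `coverage` fractions and patch bookkeeping.
#' @export
classify_patches <- function(volume, analysis_mask, model,
                             patch_size = model$patch_size, coverage = 0.5) {
  stopifnot(inherits(model, "logistic_model"))
  mask <- analysis_mask$mask
  spacing <- analysis_mask$spacing
  pf <- patch_first_order(volume$voxels, mask, spacing, patch_size, model$bin_width)
  full <- patch_size^3
  cov <- pf$count / full
  classed <- cov >= coverage
  if (!any(classed)) stop_domain("no patch reaches the coverage threshold")
  z <- apply_standardization(pf$features[classed, , drop = FALSE], model$standardization)
  prob <- predict_logistic(model, z)
  functional <- prob >= model$threshold

  # low-coverage parenchyma inherits the nearest classified patch's label
  pc_all <- arrayInd(pf$patch_id, pf$pgrid)
  centres <- (pc_all - 0.5) * patch_size
  n_fx_vox <- sum(pf$count[classed][functional])
  low <- which(!classed)
  low_fx <- logical(length(low))
  if (length(low)) {
    cc <- centres[classed, , drop = FALSE]
    for (j in seq_along(low)) {
      d2 <- rowSums(sweep(cc, 2, centres[low[j], ])^2)
      low_fx[j] <- functional[which.min(d2)]
    }
    n_fx_vox <- n_fx_vox + sum(pf$count[low][low_fx])
  }

  prob_grid <- array(NA_real_, dim = pf$pgrid)
  prob_grid[pf$patch_id[classed]] <- prob
  structure(list(prob = prob_grid, patch_size = patch_size,
                 frfx_cc = n_fx_vox * voxel_cc(spacing),
                 flr_analysed_cc = sum(pf$count) * voxel_cc(spacing),
                 coverage = cov, patch_id = pf$patch_id,
                 classified = classed, functional = functional),
            class = "functional_map")
}

#' Cross-validated balanced accuracy of the patch classifier
#'
#' Case-level folds (no patch leakage between training and validation): for
#' each fold the full selection-plus-logistic pipeline is refit on the other
#' folds' cases and evaluated on the held-out patches. Accuracy is balanced
#' (mean of per-class recalls), the convention under which a no-information
#' classifier scores 0.5 regardless of the functional/oedema imbalance.
#'
#' @param cases list of `phantom_case` objects with truth masks and images.
#' @param config see [default_classifier_config()].
#' @param n_folds number of case-level folds (capped at `length(cases)`).
#' @return Mean balanced accuracy across folds.
#' @export
cv_patch_accuracy <- function(cases, config = default_classifier_config(),
                              n_folds = 5) {
  config <- utils::modifyList(default_classifier_config(), config)
  n_folds <- min(n_folds, length(cases))
  if (n_folds < 2) stop_domain("need at least 2 folds")
  fold <- rep_len(seq_len(n_folds), length(cases))
  accs <- vapply(seq_len(n_folds), function(k) {
    fit <- train_functional_classifier(cases[fold != k], config)
    held <- do.call(rbind, lapply(cases[fold == k], function(cs) {
      do.call(rbind, lapply(c("pre", "post"), function(tp) {
        h <- harvest_case_patches(cs, tp, config)
        ok <- !is.na(h$label)
        if (!any(ok)) return(NULL)
        data.frame(h$features[ok, , drop = FALSE], label = h$label[ok])
      }))
    }))
    z <- apply_standardization(as.matrix(held[, names(held) != "label"]),
                               fit$model$standardization)
    pred <- ifelse(predict_logistic(fit$model, z) >= fit$model$threshold,
                   "functional", "oedema")
    mean(vapply(unique(held$label), function(cl)
      mean(pred[held$label == cl] == cl), numeric(1)))
  }, numeric(1))
  mean(accs)
}

#' Estimate the functional remnant volume of both timepoints
#'
#' Applies [flr_analysis_mask()] and [classify_patches()] to the pre and post
#' studies of a case.
#'
#' @param case a `phantom_case` with image volumes.
#' @param model trained `logistic_model`.
#' @param config see [default_classifier_config()].
#' @return Named numeric `c(frfx_pre_cc, frfx_post_cc)`.
#' @export
estimate_frfx <- function(case, model, config = default_classifier_config()) {
  config <- utils::modifyList(default_classifier_config(), config)
  est <- vapply(c("pre", "post"), function(tp) {
    side <- case[[tp]]
    if (is.null(side$image)) stop_domain("case has no %s image volume", tp)
    am <- flr_analysis_mask(side$seg, case_id = case$meta$case_id, timepoint = tp)
    classify_patches(side$image, am, model, coverage = config$coverage)$frfx_cc
  }, numeric(1))
  setNames(est, c("frfx_pre_cc", "frfx_post_cc"))
}
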