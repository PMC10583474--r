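# End-to-end pipeline: simulate -> train (training split) -> classify
# (held-out split) -> volumetry -> outcome tables. Every stage communicates
# through serialised artefacts and every random draw traces to a seed derived
# from the master seed.

#' Default pipeline configuration
#'
#' @param seed master integer seed.
#' @param out_dir output directory (default a tempdir subdirectory).
#' @return Named list; every field has a default and the list round-trips
#'   losslessly through JSON.
#' @export
pipeline_config <- function(seed = 1L, out_dir = file.path(tempdir(), "frfx_run")) {
  list(seed = as.integer(seed), out_dir = out_dir,
       n = 24L, split_alpps = 11L, train_fraction = 0.5,
       contrast = 1, kgr_basis = "frlv",
       classifier = default_classifier_config(),
       catalogue_version = CATALOGUE_VERSION)
}

#' Run the full simulation-to-outcome pipeline
#'
#' Generates a phantom cohort, splits it at case level (seeded shuffle) into
#' training and held-out halves, trains the functional-tissue classifier on
#' the training cases, estimates FRFx on the held-out cases, computes
#' volumetry and the primary/secondary outcome tables, and writes every
#' artefact (CSV/JSON/Markdown plus an md5 manifest) into `config$out_dir`.
#'
#' @param config list from [pipeline_config()].
#' @return Invisibly, a list with the cohort manifest, selection report,
#'   model, held-out volumetry records and outcome tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- utils::modifyList(pipeline_config(), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("pipeline seed %d\n", config$seed), file = log_path)

  spd <- list(ALPPS = default_sim_params("ALPPS", contrast = config$contrast),
              PVE = default_sim_params("PVE", contrast = config$contrast))
  cohort <- generate_cohort(config$n, c(config$split_alpps, config$n - config$split_alpps),
                            sim_params_dist = spd,
                            seed = derive_seed(config$seed, 1L, 20L), images = "both")
  write.csv(cohort$manifest, file.path(config$out_dir, "manifest.csv"), row.names = FALSE)
  logf("generated %d cases (seed stream 20)", config$n)

  n_train <- ceiling(config$n * config$train_fraction)
  perm <- with_seed(derive_seed(config$seed, 2L, 20L), sample.int(config$n))
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[-seq_len(n_train)])
  logf("train cases: %s", paste(cohort$manifest$case_id[train_idx], collapse = ","))
  logf("held-out cases: %s", paste(cohort$manifest$case_id[test_idx], collapse = ","))

  fit <- train_functional_classifier(cohort$cases[train_idx], config$classifier)
  write.csv(fit$selection, file.path(config$out_dir, "selection.csv"), row.names = FALSE)
  write_model_json(fit$model, file.path(config$out_dir, "model.json"))
  logf("selected features: %s",
       paste(fit$selection$feature[fit$selection$selected], collapse = ","))

  records <- do.call(rbind, lapply(cohort$cases[test_idx], function(cs) {
    est <- estimate_frfx(cs, fit$model, config$classifier)
    compute_volumetry(cs, frfx_pre_cc = est[["frfx_pre_cc"]],
                      frfx_post_cc = est[["frfx_post_cc"]],
                      kgr_basis = config$kgr_basis)
  }))
  write_volumetry_csv(records, file.path(config$out_dir, "volumetry.csv"))

  primary <- primary_outcome(records)
  secondary <- secondary_outcome(records)
  write.csv(primary$auc, file.path(config$out_dir, "primary_auc.csv"), row.names = FALSE)
  write.csv(primary$table, file.path(config$out_dir, "primary_table.csv"), row.names = FALSE)
  write.csv(secondary, file.path(config$out_dir, "secondary_table.csv"), row.names = FALSE)
  render_outcome_report(primary, secondary, file.path(config$out_dir, "report.md"))
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  arts <- setdiff(list.files(config$out_dir, full.names = TRUE),
                  file.path(config$out_dir, c("artifacts.csv", "run.log")))
  write.csv(data.frame(file = basename(arts), md5 = unname(tools::md5sum(arts)),
                       stringsAsFactors = FALSE),
            file.path(config$out_dir, "artifacts.csv"), row.names = FALSE)
  logf("done: %d artefacts", length(arts))

  invisible(list(manifest = cohort$manifest, selection = fit$selection,
                 model = fit$model, kmeans_rand_index = fit$kmeans_rand_index,
                 records = records, primary = primary, secondary = secondary,
                 train_idx = train_idx, test_idx = test_idx))
}
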