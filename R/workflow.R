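# End-to-end orchestration: phantom cohorts -> perfusion maps -> habitat
# model (fit on the training cohort only) -> per-habitat radiomics ->
# selection (train only) -> rebalanced grid-searched classifier -> per-cohort
# one-vs-rest evaluation -> Shapley explanation, with a run manifest.

#' Pipeline configuration
#'
#' @param cohorts List of cohort descriptors: each a list with `name`,
#'   `role` (`"train"` or `"test"`), and `n` (phantom size). Exactly one
#'   cohort must have role `"train"`.
#' @param phantom A [phantom_config()] *template*: per-cohort configs are
#'   derived from it (n and seed substream replaced per cohort).
#' @param radiomics A [radiomics_config()].
#' @param target_spacing Isotropic resampling target (mm).
#' @param k_min,k_max Habitat-count search range.
#' @param cap_per_patient Voxel pooling cap.
#' @param alpha,r_threshold Selection thresholds.
#' @param lasso_folds,cv_folds LASSO / grid-search fold counts.
#' @param grid Hyperparameter grid (default [default_xgb_grid()]).
#' @param n_boot Bootstrap replicates for AUC CIs.
#' @param seed Global seed; all stage seeds are derived substreams.
#' @param out_dir Optional output root for NIfTI / CSV / JSON artifacts.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(cohorts = list(
                              list(name = "train", role = "train", n = 90),
                              list(name = "test", role = "test", n = 45)),
                            phantom = phantom_config(),
                            radiomics = radiomics_config(),
                            target_spacing = 1,
                            k_min = 2, k_max = 10,
                            cap_per_patient = 2000,
                            alpha = 0.05, r_threshold = 0.90,
                            lasso_folds = 10, cv_folds = 5,
                            grid = default_xgb_grid(),
                            n_boot = 2000,
                            seed = 1L, out_dir = NULL) {
  roles <- vapply(cohorts, `[[`, character(1), "role")
  if (sum(roles == "train") != 1) stop("exactly one cohort must have role 'train'")
  structure(list(cohorts = cohorts, phantom = phantom, radiomics = radiomics,
                 target_spacing = target_spacing, k_min = k_min, k_max = k_max,
                 cap_per_patient = cap_per_patient, alpha = alpha,
                 r_threshold = r_threshold, lasso_folds = lasso_folds,
                 cv_folds = cv_folds, grid = grid, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Perfusion preprocessing for one study: resample all volumes to isotropic
# spacing, then compute the parametric maps on the raw resampled phases.
preprocess_study <- function(study, target_spacing) {
  if (!all(abs(study$spacing - target_spacing) < 1e-9)) {
    study$phase_pre <- resample_isotropic(study$phase_pre, study$spacing, target_spacing)
    study$phase_early <- resample_isotropic(study$phase_early, study$spacing, target_spacing)
    study$phase_delayed <- resample_isotropic(study$phase_delayed, study$spacing, target_spacing)
    study$tumor_mask <- resample_isotropic(study$tumor_mask, study$spacing,
                                           target_spacing, "nearest")
    if (!is.null(study$truth_habitats)) {
      study$truth_habitats <- resample_isotropic(study$truth_habitats, study$spacing,
                                                 target_spacing, "nearest")
    }
    study$spacing <- rep(target_spacing, 3)
  }
  study
}

#' Summarize HER2 class composition of labeled studies
#'
#' @param studies List of `dce_study` (or a character vector of labels).
#' @return Data frame: class, count, percent (2 dp).
#' @export
summarize_cohort <- function(studies) {
  labels <- if (is.character(studies)) studies else {
    vapply(studies, function(s) {
      if (is.null(s$her2) || is.na(s$her2)) stop("unlabeled study: ", s$patient_id)
      s$her2
    }, character(1))
  }
  y <- as_her2_factor(labels)
  cnt <- as.integer(table(y))
  data.frame(class = her2_levels(), count = cnt,
             percent = round(100 * cnt / length(y), 2))
}

#' Run the full habitat-radiomics pipeline
#'
#' Stages: phantom cohorts -> perfusion maps -> habitat model (fit on pooled
#' training voxels, assigned to all cohorts) -> per-habitat feature matrix
#' -> imputation and z-scoring with training statistics -> selection
#' cascade (training rows) -> rebalanced grid-searched classifier ->
#' per-cohort evaluation -> Shapley explanation of the training cohort.
#' Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress?
#' @return A `pipeline_result` with all stage outputs and a `manifest`
#'   (stage parameter echo, output hashes, timings, cohort summaries).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, stages = list())
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function(stage, value) {
    manifest$stages[[stage]] <<- list(
      hash = object_hash(value),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  }

  # --- phantom cohorts ------------------------------------------------
  say("generating %d phantom cohort(s)", length(config$cohorts))
  cohorts <- list()
  for (i in seq_along(config$cohorts)) {
    cdesc <- config$cohorts[[i]]
    pc <- config$phantom
    pc$n_patients <- as.integer(cdesc$n)
    pc$seed <- derive_seed(config$seed, paste0("cohort_", cdesc$name))
    cohorts[[cdesc$name]] <- list(
      desc = cdesc,
      studies = generate_cohort(pc, id_prefix = paste0(substr(cdesc$name, 1, 1), "_"))
    )
  }
  train_name <- vapply(config$cohorts, `[[`, character(1), "role") == "train"
  train_name <- config$cohorts[[which(train_name)]]$name
  manifest$cohort_summary <- lapply(cohorts, function(co) summarize_cohort(co$studies))
  tick("phantom", lapply(cohorts, function(co) vapply(co$studies, `[[`, character(1), "patient_id")))

  # --- perfusion -------------------------------------------------------
  say("perfusion maps")
  for (nm in names(cohorts)) {
    cohorts[[nm]]$studies <- lapply(cohorts[[nm]]$studies, preprocess_study,
                                    target_spacing = config$target_spacing)
    cohorts[[nm]]$maps <- lapply(cohorts[[nm]]$studies, function(s) {
      compute_perfusion_maps(s$phase_pre, s$phase_early, s$phase_delayed, s$tumor_mask)
    })
  }
  tick("perfusion", lapply(cohorts, function(co) length(co$maps)))

  # --- habitat model (train only) --------------------------------------
  say("habitat clustering (train cohort voxels only)")
  pool <- pool_voxel_vectors(cohorts[[train_name]]$studies,
                             cohorts[[train_name]]$maps,
                             cap_per_patient = config$cap_per_patient,
                             seed = derive_seed(config$seed, "pool"))
  model <- fit_habitat_model(pool, config$k_min, config$k_max,
                             seed = derive_seed(config$seed, "kmeans"))
  say("selected k = %d", model$k)
  for (nm in names(cohorts)) {
    cohorts[[nm]]$habitats <- mapply(assign_habitats, cohorts[[nm]]$studies,
                                     cohorts[[nm]]$maps,
                                     MoreArgs = list(model = model),
                                     SIMPLIFY = FALSE)
  }
  tick("habitats", model[c("k", "centroids", "selection_table")])

  # --- features --------------------------------------------------------
  say("radiomics feature extraction")
  mats <- list()
  for (nm in names(cohorts)) {
    mats[[nm]] <- build_feature_matrix(cohorts[[nm]]$studies,
                                       cohorts[[nm]]$habitats, model,
                                       config$radiomics)
  }
  all_mat <- do.call(rbind, lapply(names(mats), function(nm) unclass(mats[[nm]])))
  all_labels <- unlist(lapply(mats, attr, "her2"), use.names = FALSE)
  cohort_of <- rep(names(mats), vapply(mats, nrow, integer(1)))
  train_rows <- which(cohort_of == train_name)
  imp <- impute_missing(all_mat, train_rows, n_neighbors = 5)
  stats <- compute_train_stats(imp, train_rows)
  z <- zscore_transform(imp, stats)
  drop <- attr(z, "degenerate")
  if (length(drop) > 0) z <- z[, setdiff(colnames(z), drop), drop = FALSE]
  tick("features", list(dim(z), colnames(z)[seq_len(min(5, ncol(z)))]))

  # --- selection (train rows only) ------------------------------------
  say("feature selection cascade")
  sel <- select_features(z[train_rows, , drop = FALSE], all_labels[train_rows],
                         alpha = config$alpha, r_threshold = config$r_threshold,
                         n_folds = config$lasso_folds,
                         seed = derive_seed(config$seed, "selection"))
  chosen <- sel$stage3_survivors
  fallback <- FALSE
  if (length(chosen) < 2) {
    # LASSO can shrink everything away when there is no signal; fall back
    # to the best-ranked decorrelated features so evaluation stays defined
    fallback <- TRUE
    pool2 <- sel$stage2_survivors
    if (length(pool2) < 2) pool2 <- names(sort(sel$anova_pvalues))[seq_len(min(10, ncol(z)))]
    chosen <- head(pool2[order(sel$anova_pvalues[pool2])], 10)
  }
  say("selected %d features (%s)", length(chosen),
      if (fallback) "fallback" else "lasso")
  tick("selection", list(chosen = chosen, fallback = fallback,
                         n1 = length(sel$stage1_survivors),
                         n2 = length(sel$stage2_survivors)))

  # --- classify --------------------------------------------------------
  say("grid-searched gradient boosting")
  xtr <- z[train_rows, chosen, drop = FALSE]
  clf <- grid_search_train(xtr, all_labels[train_rows], grid = config$grid,
                           n_folds = config$cv_folds,
                           seed = derive_seed(config$seed, "xgb"))
  tick("classify", clf[c("best_params", "cv_macro_auc")])

  # --- evaluate per cohort ---------------------------------------------
  reports <- list()
  for (nm in names(cohorts)) {
    rows <- which(cohort_of == nm)
    pr <- predict_proba(clf, z[rows, chosen, drop = FALSE])
    reports[[nm]] <- evaluate_ovr(pr, all_labels[rows], n_boot = config$n_boot,
                                  seed = derive_seed(config$seed, paste0("eval", nm)),
                                  cohort = nm)
  }
  tick("evaluate", lapply(reports, function(r) r$macro_auc))

  # --- explain (train cohort) ------------------------------------------
  say("Shapley explanation")
  shap <- compute_shap(clf, xtr)
  tick("explain", dim(shap$phi))

  manifest$wall_clock_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res <- structure(list(
    config = config, cohorts = cohorts, habitat_model = model,
    feature_matrix = z, labels = all_labels, cohort_of = cohort_of,
    train_rows = train_rows, train_stats = stats,
    selection = sel, selected_features = chosen,
    selection_fallback = fallback,
    classifier = clf, reports = reports, shap = shap,
    manifest = manifest
  ), class = "pipeline_result")
  if (!is.null(config$out_dir)) save_pipeline_outputs(res, config$out_dir)
  res
}

# Serialize the portable pieces of a run (JSON + CSV; volumes as NIfTI).
save_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    k = res$habitat_model$k,
    centroids = res$habitat_model$centroids,
    scaler = res$habitat_model$scaler,
    selection_table = res$habitat_model$selection_table,
    fit_seed = res$habitat_model$fit_seed
  ), file.path(out_dir, "habitat_model.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(feature = res$selected_features),
            file.path(out_dir, "selected_features.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(res$reports, function(r) list(
    cohort = r$cohort, n = r$n, macro_auc = r$macro_auc,
    confusion = as.data.frame(r$confusion),
    per_class = lapply(r$per_class, function(pc)
      pc[c("auc", "ci", "accuracy", "sensitivity", "specificity", "precision", "f1")])
  )), file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  xgboost::xgb.save(res$classifier$booster, file.path(out_dir, "model.ubj"))
  invisible(out_dir)
}
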