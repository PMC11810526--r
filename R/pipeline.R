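#' Analysis run configuration
#'
#' Bundles the constants of the classification protocol: seed, conformal
#' miscoverage rate, Ct expression threshold, candidate reference assays,
#' the miRNA feature panel, the algorithm families searched, split fraction
#' and CV folds.
#'
#' @param seed Top-level seed; every stochastic stage derives its stream
#'   from it.
#' @param alpha Conformal miscoverage rate (default 0.1: a 90% guarantee).
#' @param ct_threshold Expression filter, cycles (default 35).
#' @param reference_candidates Candidate endogenous controls.
#' @param features miRNA feature panel.
#' @param families Algorithm families for the model search.
#' @param folds CV folds (default 5).
#' @param train_fraction Training share of the larger cohort (default 2/3;
#'   the remainder is the conformal calibration partition).
#' @param grids Optional named list of per-family hyperparameter grids.
#' @param model_scale Feature scale fed to the classifiers:
#'   `"neg_delta_ct"` (default; log2 relative expression, the scale on which
#'   standardized Euclidean distances behave) or `"relative"`
#'   (\eqn{2^{-\Delta Ct}}). Rank-based biomarker statistics are identical
#'   on either scale.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, alpha = 0.1, ct_threshold = 35,
                       reference_candidates = c("miR-361-5p", "miR-191-5p", "RNU48"),
                       features = default_mirnas(),
                       families = c("knn", "svm_poly", "vnn",
                                    "random_forest", "boosting"),
                       folds = 5, train_fraction = 2 / 3, grids = NULL,
                       model_scale = c("neg_delta_ct", "relative")) {
  model_scale <- match.arg(model_scale)
  if (alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must lie strictly in (0, 1).",
                 class = "mirmibc_config_error")
  }
  if (folds < 2) {
    rlang::abort("folds must be >= 2.", class = "mirmibc_config_error")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    rlang::abort("train_fraction must lie strictly in (0, 1).",
                 class = "mirmibc_config_error")
  }
  structure(list(seed = as.integer(seed), alpha = alpha,
                 ct_threshold = ct_threshold,
                 reference_candidates = reference_candidates,
                 features = features, families = families, folds = folds,
                 train_fraction = train_fraction, grids = grids,
                 model_scale = model_scale),
            class = "run_config")
}

#' Score a held-out tumour group with a frozen model
#'
#' Applies a model trained on pTa lg vs MIBC (and its conformal calibrator)
#' to samples the model never saw — the intermediate pT1 hg group. Returns
#' per-sample argmax class, class probabilities and conformal set, plus the
#' summary fractions.
#'
#' @param model Frozen fitted classifier.
#' @param calibrator Frozen `aps_calibrator`.
#' @param expr Expression table of the held-out samples (complete features).
#' @param features Feature subset of the model.
#' @return List: `predictions` (tibble), `fraction_mibc`, `singleton_rate`,
#'   `n`.
#' @export
apply_to_held_out_group <- function(model, calibrator, expr, features) {
  if (nrow(expr) == 0) {
    rlang::abort("Held-out group is empty.", class = "mirmibc_config_error")
  }
  missing_feats <- setdiff(features, names(expr))
  if (length(missing_feats) > 0) {
    rlang::abort(paste0("Held-out table lacks feature(s): ",
                        paste(missing_feats, collapse = ", ")),
                 class = "mirmibc_model_error")
  }
  use <- expr[stats::complete.cases(expr[features]), ]
  if (nrow(use) == 0) {
    rlang::abort("No held-out sample has complete features.",
                 class = "mirmibc_model_error")
  }
  p <- predict_proba(model, use[features])
  pred <- predict_class(p)
  sets <- predict_set(p, calibrator, sample_id = use$sample_id)
  predictions <- tibble::tibble(
    sample_id = use$sample_id,
    p_MIBC = p[, "MIBC"], p_pTa_lg = p[, "pTa_lg"],
    predicted = as.character(pred),
    cp_set = sets$set, is_singleton = sets$is_singleton
  )
  list(predictions = predictions,
       fraction_mibc = mean(pred == "MIBC"),
       singleton_rate = mean(sets$is_singleton),
       n = nrow(use))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates every stage on a simulated study: generate cohorts,
#' preprocess to normalized expression, per-miRNA biomarker statistics,
#' two-cohort model selection, conformal calibration of the best KNN-family
#' model, application of the frozen model to the pT1 hg group, and
#' luminal/basal subtyping of the MIBC samples. All artefacts are written
#' as CSV/JSON under `out_dir` together with a manifest recording the
#' configuration hash, seed and per-file checksums; identical configuration
#' and seed reproduce identical artefacts.
#'
#' @param gen_config A `generator_config` describing the synthetic study.
#' @param cfg A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @param frozen_family Family of the model frozen for downstream
#'   application (default `"knn"`, the study's deployed model).
#' @return Invisible list of in-memory stage results (`expression`,
#'   `stats`, `selection`, `best`, `calibrator`, `conformal`, `pt1`,
#'   `subtypes`, `manifest`).
#' @export
run_pipeline <- function(gen_config, cfg = run_config(seed = gen_config$seed),
                         out_dir, frozen_family = "knn") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  # stage 1: simulate
  sim <- generate_cohorts(gen_config)
  write_assay_records(sim$records, path("raw_records.csv"))
  readr::write_csv(sim$truth, path("latent_truth.csv"))
  panels <- generate_marker_panels(gen_config, sim$truth)
  readr::write_csv(panels, path("marker_panels.csv"))

  # stage 2: preprocess
  prep <- preprocess_records(
    sim$records, candidates = cfg$reference_candidates,
    ct_threshold = cfg$ct_threshold, assays = cfg$features)
  readr::write_csv(prep$reference_report, path("reference_report.csv"))
  readr::write_csv(prep$expression, path("expression.csv"))

  # stage 3: biomarker statistics
  stats_tbl <- biomarker_table(prep$expression, mirnas = cfg$features)
  readr::write_csv(stats_tbl, path("biomarker_stats.csv"))

  # stage 4: model selection (pT1 hg routed around training); classifiers
  # see the configured model scale (log2 of the relative expression)
  expr_model <- prep$expression
  if (cfg$model_scale == "neg_delta_ct") {
    for (m in cfg$features) expr_model[[m]] <- log2(expr_model[[m]])
  }
  expr_cls <- expr_model[expr_model$group != "pT1_hg", ]
  split <- split_cohorts(expr_cls, seed = child_seed(cfg$seed, 2),
                         train_fraction = cfg$train_fraction)
  sel <- run_model_selection(expr_cls, split, features = cfg$features,
                             families = cfg$families, folds = cfg$folds,
                             seed = child_seed(cfg$seed, 3), grids = cfg$grids)
  readr::write_csv(sel$leaderboard, path("leaderboard.csv"))
  readr::write_csv(sel$probabilities, path("probabilities.csv"))

  # stage 5: freeze the best model of the deployed family, conformal layer
  lb <- sel$leaderboard
  best_row <- lb[lb$family == frozen_family, ][1, ]
  best_cfg <- sel$configs[sel$configs$config_id == best_row$config_id, ]
  feats <- best_cfg$features[[1]]
  hp <- as.list(stats::setNames(
    as.numeric(sub(".*=", "", strsplit(best_row$hyperparams, ",")[[1]])),
    sub("=.*", "", strsplit(best_row$hyperparams, ",")[[1]])))
  tr <- expr_cls[expr_cls$sample_id %in% split$train, ]
  tr <- tr[stats::complete.cases(tr[feats]), ]
  best <- fit_classifier(make_classifier(frozen_family, hp), tr[feats],
                         tr$group, seed = child_seed(cfg$seed, 4))
  cal <- expr_cls[expr_cls$sample_id %in% split$calibration, ]
  cal <- cal[stats::complete.cases(cal[feats]), ]
  calib <- aps_calibrate(
    aps_scores(predict_proba(best, cal[feats]), cal$group), cfg$alpha)
  te <- expr_cls[expr_cls$sample_id %in% split$test, ]
  te <- te[stats::complete.cases(te[feats]), ]
  sets <- predict_set(predict_proba(best, te[feats]), calib,
                      sample_id = te$sample_id)
  readr::write_csv(sets[c("sample_id", "set", "p_first", "p_second",
                          "is_singleton")],
                   path("prediction_sets.csv"))
  cov <- coverage_report(sets, te$group)
  write_json_report(
    c(cov, list(alpha = cfg$alpha, qhat = calib$qhat,
                model = paste0(best_row$subset_label, "/", frozen_family))),
    path("coverage.json"))

  # stage 6: frozen model on the pT1 hg group
  pt1 <- expr_model[expr_model$group == "pT1_hg", ]
  pt1_res <- NULL
  if (nrow(pt1) > 0) {
    pt1_res <- apply_to_held_out_group(best, calib, pt1, feats)
    readr::write_csv(pt1_res$predictions, path("pt1_predictions.csv"))
    write_json_report(
      list(fraction_predicted_mibc = pt1_res$fraction_mibc,
           singleton_rate = pt1_res$singleton_rate, n = pt1_res$n),
      path("pt1_summary.json"))
  }

  # stage 7: luminal/basal subtyping of MIBC samples
  z <- zscore_markers(panels)
  subtypes <- ward_subtype(z)
  sub_tbl <- tibble::tibble(tumour_id = panels$tumour_id,
                            subtype = as.character(subtypes))
  readr::write_csv(sub_tbl, path("subtype_labels.csv"))
  mibc_expr <- prep$expression[prep$expression$sample_id %in% panels$tumour_id, ]
  cmp <- compare_by_subtype(
    mibc_expr, stats::setNames(as.character(subtypes), panels$tumour_id),
    mirnas = cfg$features)
  readr::write_csv(cmp, path("subtype_comparisons.csv"))

  # manifest: config hash, seed, per-file checksums
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    config_hash = rlang::hash(list(gen_config, unclass(cfg))),
    seed = cfg$seed,
    reference = prep$reference,
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(path(f)))
    })
  )
  write_json_report(manifest, path("manifest.json"))

  invisible(list(expression = prep$expression, stats = stats_tbl,
                 selection = sel, split = split, best = best,
                 calibrator = calib, conformal = cov, pt1 = pt1_res,
                 subtypes = sub_tbl, manifest = manifest))
}
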