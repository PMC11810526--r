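#' Split two cohorts into train / calibration / test
#'
#' The study protocol: the larger cohort is partitioned, stratified by class,
#' into two-thirds training and one-third calibration (the conformal
#' calibration data); the smaller cohort is the test set in full. pT1 hg
#' samples are excluded — they are scored later by the frozen model, never
#' used for fitting.
#'
#' @param expr Expression table with `sample_id`, `cohort`, `group` columns
#'   and exactly two cohorts containing pTa lg and MIBC samples.
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @param train_fraction Fraction of the larger cohort used for training
#'   (default 2/3).
#' @return A `cohort_split`: list of `sample_id` vectors `train`,
#'   `calibration`, `test`, plus `larger_cohort`, a `stratification` count
#'   table and the `seed`.
#' @export
split_cohorts <- function(expr, seed = 1L, train_fraction = 2 / 3) {
  cls <- expr[expr$group %in% c("pTa_lg", "MIBC"), ]
  cohorts <- sort(unique(cls$cohort))
  if (length(cohorts) != 2) {
    rlang::abort("Exactly two cohorts with classification samples are required.",
                 class = "mirmibc_config_error")
  }
  for (co in cohorts) {
    present <- unique(cls$group[cls$cohort == co])
    if (!all(c("pTa_lg", "MIBC") %in% present)) {
      rlang::abort(paste0("Cohort '", co, "' is missing one of the classes."),
                   class = "mirmibc_config_error")
    }
  }
  sizes <- table(cls$cohort)
  larger <- names(sizes)[which.max(sizes)]
  smaller <- setdiff(cohorts, larger)
  big <- cls[cls$cohort == larger, ]
  withr::with_seed(seed, {
    train_ids <- unlist(lapply(c("MIBC", "pTa_lg"), function(g) {
      ids <- big$sample_id[big$group == g]
      sample(ids, size = round(length(ids) * train_fraction))
    }), use.names = FALSE)
  })
  cal_ids <- setdiff(big$sample_id, train_ids)
  test_ids <- cls$sample_id[cls$cohort == smaller]
  strat <- as.data.frame(table(
    partition = rep(c("train", "calibration", "test"),
                    c(length(train_ids), length(cal_ids), length(test_ids))),
    group = cls$group[match(c(train_ids, cal_ids, test_ids), cls$sample_id)]))
  structure(
    list(train = sort(train_ids), calibration = sort(cal_ids),
         test = sort(test_ids), larger_cohort = larger,
         stratification = strat, seed = as.integer(seed)),
    class = "cohort_split")
}

#' Enumerate (feature subset, family) model configurations
#'
#' All non-empty subsets of the feature panel crossed with every algorithm
#' family, in deterministic canonical order: subsets by size then
#' lexicographically by feature position, families in their declared order
#' within each subset.
#'
#' @param features Character vector of feature (miRNA) names.
#' @param families Algorithm families (default the five used in the search).
#' @return Tibble: `config_id`, `features` (list column), `subset_label`,
#'   `subset_size`, `family`.
#' @export
enumerate_configs <- function(features,
                              families = c("knn", "svm_poly", "vnn",
                                           "random_forest", "boosting")) {
  m <- length(features)
  stopifnot(m >= 1)
  subsets <- unlist(lapply(seq_len(m), function(s) {
    combn(features, s, simplify = FALSE)
  }), recursive = FALSE)
  grid <- tidyr::expand_grid(subset = seq_along(subsets), family = families)
  tibble::tibble(
    config_id = seq_len(nrow(grid)),
    features = subsets[grid$subset],
    subset_label = vapply(subsets[grid$subset], paste, character(1), collapse = "+"),
    subset_size = lengths(subsets[grid$subset]),
    family = grid$family
  )
}

#' Default hyperparameter grids per family
#'
#' The search grids used during cross-validation. Each grid contains the
#' study's printed best value for its family, so the reported models are
#' reachable. Candidate order is canonical: ties in CV AUC resolve to the
#' earliest row.
#'
#' @param family Algorithm family name.
#' @return Data frame, one row per hyperparameter candidate.
#' @export
default_grid <- function(family) {
  switch(family,
    knn = data.frame(k = seq(1, 31, by = 2)),
    svm_poly = expand.grid(C = c(0.1, 1, 10), degree = c(2, 3),
                           scale = c(0.01, 0.1, 1)),
    vnn = expand.grid(size = c(2, 4, 8), decay = c(0.001, 0.01, 0.1)),
    random_forest = data.frame(ntree = c(100, 500)),
    boosting = data.frame(nrounds = c(100, 500)),
    rlang::abort(paste0("Unknown family '", family, "'."),
                 class = "mirmibc_model_error")
  )
}

# stratified fold assignment; every class spread as evenly as possible
make_stratified_folds <- function(y, folds, seed) {
  y <- as_class_factor(y)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (g in levels(y)) {
      idx <- which(y == g)
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  fold
}

#' Tune hyperparameters by stratified fivefold cross-validated AUC
#'
#' For each grid candidate, fits on four folds and scores the held-out fold;
#' the selection criterion is the mean out-of-fold AUC of the MIBC
#' probability. Ties resolve to the earliest candidate in canonical grid
#' order. Folds are stratified by class; a fold whose held-out part lacks a
#' class contributes no AUC (and an error is raised if no fold is scoreable).
#'
#' @param family Algorithm family.
#' @param x,y Training features and labels.
#' @param grid Candidate grid (default [default_grid()]).
#' @param folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and fit randomness.
#' @return List: `best` (named list of winning hyperparameters), `cv_auc`,
#'   `results` (per-candidate tibble).
#' @export
cv_tune <- function(family, x, y, grid = default_grid(family),
                    folds = 5, seed = 1L) {
  x <- as.matrix(x)
  y <- as_class_factor(y)
  stopifnot(folds >= 2)
  if (nlevels(droplevels(y)) < 2) {
    rlang::abort("Training data must contain both classes.",
                 class = "mirmibc_model_error")
  }
  fold <- make_stratified_folds(y, folds, seed)
  min_fit_n <- min(vapply(seq_len(folds), function(f) sum(fold != f), integer(1)))
  if (family == "knn") grid <- grid[grid$k <= min_fit_n, , drop = FALSE]
  if (nrow(grid) == 0) {
    rlang::abort("No feasible hyperparameter candidate for the fold sizes.",
                 class = "mirmibc_model_error")
  }
  aucs <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- make_classifier(family, as.list(grid[i, , drop = FALSE]))
    fold_auc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      if (nlevels(droplevels(y[!tr])) < 2) return(NA_real_)
      fit <- fit_classifier(spec, x[tr, , drop = FALSE], y[tr],
                            seed = child_seed(seed, f))
      p <- predict_proba(fit, x[!tr, , drop = FALSE])
      roc_auc(p[, "MIBC"], y[!tr], positive = "MIBC")$auc
    }, numeric(1))
    if (all(is.na(fold_auc))) {
      rlang::abort("No cross-validation fold contained both classes.",
                   class = "mirmibc_model_error")
    }
    mean(fold_auc, na.rm = TRUE)
  }, numeric(1))
  best_i <- which.max(aucs) # which.max takes the first maximum: canonical tie rule
  results <- tibble::as_tibble(grid)
  results$cv_auc <- aucs
  list(best = as.list(grid[best_i, , drop = FALSE]), cv_auc = aucs[best_i],
       results = results)
}

#' Evaluate a fitted model on a test set
#'
#' Confusion-matrix metrics under the study's conventions: sensitivity is
#' the fraction of MIBC samples classified correctly, specificity the
#' fraction of pTa lg samples classified correctly. `source_filter = "TURB"`
#' restricts scoring to TURB specimens, the pre-surgery decision setting.
#'
#' @param model Fitted classifier.
#' @param x Test features.
#' @param y Test labels.
#' @param source Optional per-sample specimen source (required when
#'   filtering).
#' @param source_filter Optional subset of sources to score (e.g. `"TURB"`).
#' @return List: `accuracy`, `sensitivity`, `specificity`, `n`, `confusion`
#'   (table), `probabilities`.
#' @export
evaluate_model <- function(model, x, y, source = NULL, source_filter = NULL) {
  x <- as.matrix(x)
  y <- as_class_factor(y)
  if (!is.null(source_filter)) {
    if (is.null(source)) {
      rlang::abort("source must be supplied when source_filter is used.",
                   class = "mirmibc_config_error")
    }
    keep <- source %in% source_filter
    if (!any(keep)) {
      rlang::abort("No test samples left after the source filter.",
                   class = "mirmibc_config_error")
    }
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  p <- predict_proba(model, x)
  pred <- predict_class(p)
  conf <- table(truth = y, predicted = pred)
  sens <- mean(pred[y == "MIBC"] == "MIBC")
  spec <- mean(pred[y == "pTa_lg"] == "pTa_lg")
  list(accuracy = mean(pred == y), sensitivity = sens, specificity = spec,
       n = length(y), confusion = conf, probabilities = p)
}

#' Rank model evaluations into a leaderboard
#'
#' Deterministic ordering: accuracy (descending), then sensitivity
#' (descending), then smaller feature subset, then canonical configuration
#' order. The study reports co-equal best models; determinism here comes
#' from the documented tie-breaks.
#'
#' @param evaluations Tibble with at least `accuracy`, `sensitivity`,
#'   `subset_size`, `config_id`.
#' @return The tibble sorted, with a `rank` column prepended.
#' @export
rank_models <- function(evaluations) {
  stopifnot(nrow(evaluations) >= 1)
  lb <- dplyr::arrange(evaluations, dplyr::desc(.data$accuracy),
                       dplyr::desc(.data$sensitivity), .data$subset_size,
                       .data$config_id)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(lb))), lb)
}

#' Count leaderboard models above an accuracy threshold
#'
#' @param leaderboard Output of [rank_models()].
#' @param threshold Accuracy threshold.
#' @return Number of models with accuracy strictly above the threshold.
#' @export
models_above <- function(leaderboard, threshold) {
  sum(leaderboard$accuracy > threshold)
}

#' Run the exhaustive model search over feature subsets and families
#'
#' For every configuration from [enumerate_configs()]: restrict to samples
#' with complete features for that subset, tune hyperparameters by
#' cross-validated AUC on the training partition, refit on the full training
#' partition, and evaluate on the full test cohort and on its TURB-only
#' subset. Samples with a missing modelling feature are excluded per
#' configuration with a logged count.
#'
#' @param expr Expression table.
#' @param split A `cohort_split`.
#' @param features Feature panel (default the four study miRNAs present in
#'   `expr`).
#' @param families Algorithm families to search.
#' @param folds CV folds (default 5).
#' @param seed Seed for fold assignment and stochastic fits.
#' @param grids Optional named list of per-family hyperparameter grids.
#' @return List: `leaderboard`, `evaluations`, `probabilities` (long per-test
#'   -sample table), `configs`.
#' @export
run_model_selection <- function(expr, split, features = NULL,
                                families = c("knn", "svm_poly", "vnn",
                                             "random_forest", "boosting"),
                                folds = 5, seed = 1L, grids = NULL) {
  meta <- c("sample_id", "cohort", "group", "source")
  if (is.null(features)) features <- setdiff(names(expr), meta)
  configs <- enumerate_configs(features, families)
  rows <- list()
  probs <- list()
  for (i in seq_len(nrow(configs))) {
    feats <- configs$features[[i]]
    family <- configs$family[i]
    grid <- if (!is.null(grids) && family %in% names(grids)) {
      grids[[family]]
    } else {
      default_grid(family)
    }
    use <- expr[stats::complete.cases(expr[feats]), ]
    n_dropped <- nrow(expr) - nrow(use)
    tr <- use[use$sample_id %in% split$train, ]
    te <- use[use$sample_id %in% split$test, ]
    tuned <- cv_tune(family, tr[feats], tr$group, grid = grid,
                     folds = folds, seed = child_seed(seed, i))
    spec <- make_classifier(family, tuned$best)
    fit <- fit_classifier(spec, tr[feats], tr$group,
                          seed = child_seed(seed, 100000 + i))
    ev <- evaluate_model(fit, te[feats], te$group)
    ev_turb <- evaluate_model(fit, te[feats], te$group,
                              source = te$source, source_filter = "TURB")
    rows[[i]] <- tibble::tibble(
      config_id = configs$config_id[i],
      subset_label = configs$subset_label[i],
      subset_size = configs$subset_size[i],
      family = family,
      hyperparams = paste(names(tuned$best), unlist(tuned$best),
                          sep = "=", collapse = ","),
      cv_auc = tuned$cv_auc,
      accuracy = ev$accuracy, sensitivity = ev$sensitivity,
      specificity = ev$specificity,
      accuracy_turb = ev_turb$accuracy, sensitivity_turb = ev_turb$sensitivity,
      specificity_turb = ev_turb$specificity,
      n_test = ev$n, n_dropped_missing = n_dropped
    )
    probs[[i]] <- tibble::tibble(
      sample_id = te$sample_id, config_id = configs$config_id[i],
      model_id = paste0(configs$subset_label[i], "/", family),
      p_MIBC = ev$probabilities[, "MIBC"],
      p_pTa_lg = ev$probabilities[, "pTa_lg"],
      predicted = as.character(predict_class(ev$probabilities)),
      truth = te$group
    )
  }
  evaluations <- dplyr::bind_rows(rows)
  list(leaderboard = rank_models(evaluations), evaluations = evaluations,
       probabilities = dplyr::bind_rows(probs), configs = configs)
}
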