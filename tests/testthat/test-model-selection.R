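test_that("the cohort split follows the 2/3 : 1/3 : smaller-cohort protocol", {
  cfg <- generator_config(seed = 4)
  sim <- generate_cohorts(cfg)
  expr <- preprocess_records(sim$records, reference = "miR-361-5p",
                             assays = cfg$mirnas)$expression
  expr <- expr[expr$group != "pT1_hg", ]
  split <- split_cohorts(expr, seed = 10)
  expect_equal(length(split$train), 122)
  expect_equal(length(split$calibration), 61)
  expect_equal(length(split$test), 66)
  expect_equal(split$larger_cohort, "cohort2")
  # disjointness and cohort containment
  expect_length(intersect(split$train, split$calibration), 0)
  expect_length(intersect(c(split$train, split$calibration), split$test), 0)
  expect_true(all(expr$cohort[match(split$test, expr$sample_id)] == "cohort1"))
  # class stratification preserved within one sample
  grp <- expr$group[match(split$train, expr$sample_id)]
  expect_equal(sum(grp == "MIBC"), round(100 * 2 / 3))
  expect_equal(sum(grp == "pTa_lg"), round(83 * 2 / 3))
  # determinism
  expect_identical(split_cohorts(expr, seed = 10)[1:3], split[1:3])
  expect_false(identical(split_cohorts(expr, seed = 11)$train, split$train))
})

test_that("a cohort missing one class is rejected", {
  expr <- toy_expression()
  broken <- expr[!(expr$cohort == "c1" & expr$group == "MIBC"), ]
  expect_error(split_cohorts(broken), class = "mirmibc_config_error")
})

test_that("configuration enumeration is exhaustive and canonical", {
  mirnas <- paste0("m", 1:4)
  cfgs <- enumerate_configs(mirnas)
  expect_equal(nrow(cfgs), 75) # 15 subsets x 5 families
  expect_equal(length(unique(cfgs$subset_label)), 15)
  expect_equal(nrow(enumerate_configs("m1")), 5)
  expect_equal(nrow(enumerate_configs(mirnas, families = "knn")), 15)
  # canonical order: subset sizes non-decreasing, deterministic ids
  expect_true(all(diff(cfgs$subset_size) >= 0))
  expect_identical(cfgs, enumerate_configs(mirnas))
})

test_that("cv_tune maximizes out-of-fold AUC deterministically", {
  expr <- toy_expression(seed = 3, n1 = 10, n2 = 60, shift = 6)
  tr <- expr[expr$cohort == "c2", ]
  one <- cv_tune("knn", tr["mirA"], tr$group, grid = data.frame(k = 5),
                 folds = 5, seed = 2)
  expect_equal(one$best$k, 5)
  # essentially separable data: the winner reaches CV AUC 1
  tuned <- cv_tune("knn", tr["mirA"], tr$group, folds = 5, seed = 2)
  expect_equal(tuned$cv_auc, 1.0)
  again <- cv_tune("knn", tr["mirA"], tr$group, folds = 5, seed = 2)
  expect_identical(tuned$best, again$best)
  expect_identical(tuned$cv_auc, again$cv_auc)
  # infeasible k candidates are not considered
  idx <- c(1:6, 31:36) # six of each class
  small <- cv_tune("knn", tr[idx, "mirA"], tr$group[idx],
                   grid = data.frame(k = c(3, 99)), folds = 3, seed = 1)
  expect_equal(small$best$k, 3)
})

test_that("evaluation metrics follow the study's confusion-matrix conventions", {
  # build a fake perfectly-known probability pattern via a k=1 knn
  x <- matrix(c(0, 1, 10, 11), 4, 1, dimnames = list(NULL, "f"))
  y <- c("MIBC", "MIBC", "pTa_lg", "pTa_lg")
  m <- knn_fit(x, y, 1)
  ev <- evaluate_model(m, x, y)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  # TP 9, FN 1, TN 8, FP 2 -> sens 0.9, spec 0.8, acc 0.85
  xt <- matrix(c(seq(0, 0.8, length.out = 9), 10,
                 seq(10.1, 10.8, length.out = 8), 0.4, 0.5), 20, 1,
               dimnames = list(NULL, "f"))
  yt <- rep(c("MIBC", "pTa_lg"), c(10, 10))
  ev2 <- evaluate_model(m, xt, yt)
  expect_equal(ev2$sensitivity, 0.9)
  expect_equal(ev2$specificity, 0.8)
  expect_equal(ev2$accuracy, 0.85)
  # metric identity: accuracy is the class-weighted mean of sens and spec
  n_mibc <- sum(yt == "MIBC"); n_pta <- sum(yt == "pTa_lg")
  expect_equal(ev2$accuracy,
               (ev2$sensitivity * n_mibc + ev2$specificity * n_pta) /
                 (n_mibc + n_pta))
})

test_that("TURB-only evaluation filters sources; empty filters error", {
  x <- matrix(c(0, 1, 10, 11), 4, 1, dimnames = list(NULL, "f"))
  y <- c("MIBC", "MIBC", "pTa_lg", "pTa_lg")
  m <- knn_fit(x, y, 1)
  src <- c("CYS", "TURB", "TURB", "TURB")
  ev <- evaluate_model(m, x, y, source = src, source_filter = "TURB")
  expect_equal(ev$n, 3)
  expect_error(
    evaluate_model(m, x, y, source = rep("CYS", 4), source_filter = "TURB"),
    class = "mirmibc_config_error")
  expect_error(evaluate_model(m, x, y, source_filter = "TURB"),
               class = "mirmibc_config_error")
})

test_that("specificity is identical with and without the TURB filter when pTa lg has no CYS", {
  expr <- toy_expression(seed = 8, n1 = 30, n2 = 48, shift = 2)
  expect_true(all(expr$source[expr$group == "pTa_lg"] == "TURB"))
  split <- split_cohorts(expr, seed = 1)
  tr <- expr[expr$sample_id %in% split$train, ]
  te <- expr[expr$sample_id %in% split$test, ]
  feats <- c("mirA", "mirB")
  m <- fit_classifier(make_classifier("knn", list(k = 5)), tr[feats], tr$group)
  full <- evaluate_model(m, te[feats], te$group)
  turb <- evaluate_model(m, te[feats], te$group, source = te$source,
                         source_filter = "TURB")
  expect_equal(turb$specificity, full$specificity)
})

test_that("the leaderboard ranks deterministically and counts thresholds", {
  evals <- tibble::tibble(
    config_id = 1:4,
    subset_label = c("a", "b", "a+b", "c"),
    subset_size = c(1, 1, 2, 1),
    accuracy = c(0.91, 0.94, 0.94, 0.85),
    sensitivity = c(0.9, 0.92, 0.95, 0.8))
  lb <- rank_models(evals)
  expect_equal(lb$config_id, c(3, 2, 1, 4)) # accuracy, then sensitivity
  expect_equal(lb$rank, 1:4)
  expect_equal(models_above(lb, 0.85), sum(evals$accuracy > 0.85))
  expect_equal(models_above(lb, 0.85), 3)
  single <- rank_models(evals[2, ])
  expect_equal(nrow(single), 1)
})

test_that("the full search recovers a planted strong marker", {
  expr <- toy_expression(seed = 5, n1 = 24, n2 = 48, shift = 3)
  split <- split_cohorts(expr, seed = 2)
  res <- run_model_selection(
    expr, split, features = c("mirA", "mirB", "mirC"), families = "knn",
    folds = 3, seed = 7, grids = list(knn = data.frame(k = c(3, 7))))
  expect_equal(nrow(res$leaderboard), 7) # 2^3 - 1 subsets x 1 family
  expect_match(res$leaderboard$subset_label[1], "mirA")
  # metric identity holds on every evaluation row
  n_te <- length(split$test)
  probs <- res$probabilities
  n_mibc <- sum(probs$truth[probs$config_id == 1] == "MIBC")
  ev <- res$evaluations
  expect_equal(ev$accuracy,
               (ev$sensitivity * n_mibc + ev$specificity * (n_te - n_mibc)) /
                 n_te)
  # per-sample probability artefact covers every (test sample, config)
  expect_equal(nrow(probs), 7 * n_te)
  expect_true(all(abs(probs$p_MIBC + probs$p_pTa_lg - 1) < 1e-12))
})
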