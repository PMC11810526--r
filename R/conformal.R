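# descending-probability class order with the canonical tie-break
aps_class_order <- function(p_row) {
  order(-p_row, seq_along(p_row)) # equal probabilities -> canonical order
}

#' Adaptive-prediction-sets conformity scores
#'
#' For each calibration sample the score is the cumulative predicted
#' probability of all classes ranked at or above the true class (descending
#' probability, exact ties broken by the canonical class order MIBC before
#' pTa lg). In the binary case this reduces to: p(true class) when the true
#' class is the argmax, else 1.
#'
#' @param probabilities Matrix of class probabilities (columns `MIBC`,
#'   `pTa_lg`), rows summing to 1.
#' @param true_labels Known labels for the calibration samples.
#' @return Numeric vector of scores in (0, 1].
#' @export
aps_scores <- function(probabilities, true_labels) {
  p <- probabilities[, mibc_classes(), drop = FALSE]
  y <- as_class_factor(true_labels)
  if (nrow(p) != length(y)) {
    rlang::abort("probabilities and true_labels are not aligned.",
                 class = "mirmibc_conformal_error")
  }
  vapply(seq_len(nrow(p)), function(i) {
    ord <- aps_class_order(p[i, ])
    pos <- which(mibc_classes()[ord] == as.character(y[i]))
    sum(p[i, ord[seq_len(pos)]])
  }, numeric(1))
}

#' Calibrate the APS threshold
#'
#' Conservative split-conformal quantile: with n calibration scores, the
#' threshold q-hat is the ceiling((n + 1) * (1 - alpha))-th smallest score,
#' clipped to 1 when that index exceeds n. Prediction sets built with this
#' threshold contain the true class with marginal probability at least
#' 1 - alpha for exchangeable data.
#'
#' @param scores Calibration scores from [aps_scores()].
#' @param alpha Miscoverage rate in (0, 1) (default 0.1, i.e. a 90%
#'   guarantee).
#' @return An `aps_calibrator`: list with `qhat`, `alpha`, `n_cal`.
#' @export
aps_calibrate <- function(scores, alpha = 0.1) {
  if (length(scores) < 1) {
    rlang::abort("Need at least one calibration score.",
                 class = "mirmibc_conformal_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must lie strictly between 0 and 1.",
                 class = "mirmibc_conformal_error")
  }
  n <- length(scores)
  idx <- ceiling((n + 1) * (1 - alpha))
  qhat <- if (idx > n) 1 else sort(scores)[idx]
  structure(list(qhat = qhat, alpha = alpha, n_cal = n),
            class = "aps_calibrator")
}

#' @export
print.aps_calibrator <- function(x, ...) {
  cat(sprintf("APS calibrator: qhat = %.4f (alpha = %g, n_cal = %d)\n",
              x$qhat, x$alpha, x$n_cal))
  invisible(x)
}

#' Conformal prediction sets
#'
#' Classes are added in descending predicted probability until the
#' cumulative probability reaches the threshold (boundary included): a
#' sample whose top probability is greater than or equal to q-hat gets that
#' single class; otherwise both classes, the higher-probability class listed
#' first.
#'
#' @param probabilities Probability matrix (columns `MIBC`, `pTa_lg`).
#' @param calibrator An `aps_calibrator`.
#' @param sample_id Optional sample identifiers.
#' @return Tibble: `sample_id`, `set` (classes joined by `|`), `classes`
#'   (list column, descending probability), `p_first`, `p_second`
#'   (`NA` for singletons), `is_singleton`.
#' @export
predict_set <- function(probabilities, calibrator, sample_id = NULL) {
  stopifnot(inherits(calibrator, "aps_calibrator"))
  p <- probabilities[, mibc_classes(), drop = FALSE]
  if (is.null(sample_id)) {
    sample_id <- rownames(p) %||% as.character(seq_len(nrow(p)))
  }
  res <- lapply(seq_len(nrow(p)), function(i) {
    ord <- aps_class_order(p[i, ])
    cum <- cumsum(p[i, ord])
    take <- seq_len(match(TRUE, cum >= calibrator$qhat, nomatch = length(ord)))
    list(classes = mibc_classes()[ord[take]], probs = unname(p[i, ord[take]]))
  })
  tibble::tibble(
    sample_id = sample_id,
    set = vapply(res, function(r) paste(r$classes, collapse = "|"), character(1)),
    classes = lapply(res, `[[`, "classes"),
    p_first = vapply(res, function(r) r$probs[1], numeric(1)),
    p_second = vapply(res, function(r) {
      if (length(r$probs) > 1) r$probs[2] else NA_real_
    }, numeric(1)),
    is_singleton = vapply(res, function(r) length(r$classes) == 1, logical(1))
  )
}

#' Empirical coverage of conformal prediction sets
#'
#' @param sets Prediction-set tibble from [predict_set()].
#' @param true_labels Labels aligned with the sets.
#' @return List: `coverage` (fraction of sets containing the truth),
#'   `singleton_rate`, `singleton_accuracy` (`NA` when there are no
#'   singletons), `n`.
#' @export
coverage_report <- function(sets, true_labels) {
  y <- as.character(as_class_factor(true_labels))
  if (nrow(sets) != length(y)) {
    rlang::abort("sets and true_labels are not aligned.",
                 class = "mirmibc_conformal_error")
  }
  contains <- mapply(function(cl, t) t %in% cl, sets$classes, y)
  singles <- sets$is_singleton
  singleton_acc <- if (any(singles)) {
    mean(vapply(which(singles), function(i) sets$classes[[i]][1] == y[i],
                logical(1)))
  } else {
    NA_real_
  }
  list(coverage = mean(contains), singleton_rate = mean(singles),
       singleton_accuracy = singleton_acc, n = length(y))
}

#' Replicated coverage experiment for the conformal layer
#'
#' Monte-Carlo check of the marginal coverage guarantee under the synthetic
#' study design: a KNN model is trained once on the training partition of a
#' default two-cohort simulation; then, for each replicate, a fresh
#' calibration cohort and a fresh test cohort are generated from the same
#' distribution, the APS threshold is calibrated at `alpha`, and the
#' fraction of test prediction sets containing the true class is recorded.
#'
#' @param n_replicates Number of calibration/test replicate draws.
#' @param n_test Test-cohort size per replicate.
#' @param alpha Miscoverage rate.
#' @param k KNN neighbour count.
#' @param features Feature panel for the KNN (default the study's best
#'   three-miRNA signature).
#' @param seed Top-level seed for the training draw and all replicates.
#' @param n_cal Calibration size per replicate; default the size of the
#'   training split's calibration partition (61 under the default design).
#' @return List: `mean_coverage`, `coverage` (per replicate),
#'   `singleton_rate` (per replicate), `qhat` (per replicate), `n_train`,
#'   `n_cal`, `n_test`.
#' @export
coverage_experiment <- function(n_replicates = 500, n_test = 2000,
                                alpha = 0.1, k = 19,
                                features = c("miR-138-5p", "miR-146b-5p",
                                             "miR-200a-3p"),
                                seed = 1L, n_cal = NULL) {
  cfg <- generator_config(seed = child_seed(seed, 0))
  sim <- generate_cohorts(cfg)
  prep <- preprocess_records(sim$records, reference = "miR-361-5p",
                             assays = cfg$mirnas, scale = "neg_delta_ct")
  expr <- prep$expression
  split <- split_cohorts(expr[expr$group != "pT1_hg", ], seed = child_seed(seed, 1))
  tr <- expr[expr$sample_id %in% split$train, ]
  tr <- tr[stats::complete.cases(tr[features]), ]
  model <- knn_fit(tr[features], tr$group, k = k)

  # class composition for the replicate draws mirrors the fitted design:
  # calibration at the calibration partition's ratio, test at the larger
  # cohort's ratio
  cal_groups <- expr$group[match(split$calibration, expr$sample_id)]
  if (is.null(n_cal)) n_cal <- length(split$calibration)
  cal_mibc <- round(n_cal * mean(cal_groups == "MIBC"))
  big <- expr[expr$cohort == split$larger_cohort & expr$group != "pT1_hg", ]
  test_mibc <- round(n_test * mean(big$group == "MIBC"))

  cov <- single <- qh <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    rcfg <- generator_config(
      seed = child_seed(seed, 10 + r),
      cohorts = list(
        cal = c(pTa_lg = n_cal - cal_mibc, pT1_hg = 0, MIBC = cal_mibc),
        test = c(pTa_lg = n_test - test_mibc, pT1_hg = 0, MIBC = test_mibc)
      )
    )
    rsim <- generate_cohorts(rcfg)
    rexpr <- preprocess_records(rsim$records, reference = "miR-361-5p",
                                assays = cfg$mirnas,
                                scale = "neg_delta_ct")$expression
    rexpr <- rexpr[stats::complete.cases(rexpr[features]), ]
    cal <- rexpr[rexpr$cohort == "cal", ]
    te <- rexpr[rexpr$cohort == "test", ]
    calib <- aps_calibrate(
      aps_scores(knn_predict_proba(model, cal[features]), cal$group), alpha)
    sets <- predict_set(knn_predict_proba(model, te[features]), calib,
                        sample_id = te$sample_id)
    rep_cov <- coverage_report(sets, te$group)
    cov[r] <- rep_cov$coverage
    single[r] <- rep_cov$singleton_rate
    qh[r] <- calib$qhat
  }
  list(mean_coverage = mean(cov), coverage = cov, singleton_rate = single,
       qhat = qh, n_train = nrow(tr), n_cal = n_cal, n_test = n_test,
       alpha = alpha, k = k, features = features)
}
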