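#!/usr/bin/env Rscript
# Stage 5 — conformal layer: refit the best KNN-family model from the
# leaderboard on the training partition, calibrate the adaptive-prediction-
# sets threshold at alpha = 0.1 on the calibration partition, and emit
# per-sample prediction sets and the coverage report for the test cohort.

library(mirmibc)

seed <- 1L
alpha <- 0.1
expr <- readr::read_csv("results/expression_model.csv", show_col_types = FALSE)
split <- readr::read_csv("results/split.csv", show_col_types = FALSE)
lb <- readr::read_csv("results/leaderboard.csv", show_col_types = FALSE)

best <- lb[lb$family == "knn", ][1, ]
feats <- strsplit(best$subset_label, "+", fixed = TRUE)[[1]]
k <- as.numeric(sub("k=", "", best$hyperparams))
message("Frozen model: KNN k = ", k, " on {", paste(feats, collapse = ", "),
        "} (test accuracy ", round(best$accuracy, 3), ").")

part <- function(p) {
  s <- expr[expr$sample_id %in% split$sample_id[split$partition == p], ]
  s[stats::complete.cases(s[feats]), ]
}
tr <- part("train"); cal <- part("calibration"); te <- part("test")

model <- fit_classifier(make_classifier("knn", list(k = k)),
                        tr[feats], tr$group)
calib <- aps_calibrate(aps_scores(predict_proba(model, cal[feats]),
                                  cal$group), alpha)
print(calib)

sets <- predict_set(predict_proba(model, te[feats]), calib,
                    sample_id = te$sample_id)
readr::write_csv(sets[c("sample_id", "set", "p_first", "p_second",
                        "is_singleton")], "results/prediction_sets.csv")
rep <- coverage_report(sets, te$group)
jsonlite::write_json(c(rep, list(alpha = alpha, qhat = calib$qhat, k = k,
                                 features = paste(feats, collapse = "+"))),
                     "results/coverage.json", auto_unbox = TRUE, digits = NA)
message(sprintf(
  "Test-cohort conformal report: coverage %.3f, singleton rate %.3f, singleton accuracy %s (n = %d).",
  rep$coverage, rep$singleton_rate,
  ifelse(is.na(rep$singleton_accuracy), "NA",
         sprintf("%.3f", rep$singleton_accuracy)), rep$n))
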