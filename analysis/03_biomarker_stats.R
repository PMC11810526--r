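#!/usr/bin/env Rscript
# Stage 3 — single-marker statistics: per-cohort, source-stratified
# Mann-Whitney comparisons of pTa lg vs MIBC with ROC AUCs for each miRNA,
# the three-group Kruskal-Wallis test including pT1 hg, and the
# miR-146b/miR-155 expression correlation.

library(mirmibc)

expr <- readr::read_csv("results/expression.csv", show_col_types = FALSE)
targets <- c("miR-138-5p", "miR-146b-5p", "miR-155-5p", "miR-200a-3p")

tbl <- biomarker_table(expr, mirnas = targets)
readr::write_csv(tbl, "results/biomarker_stats.csv")
message("Per-miRNA pTa lg vs MIBC statistics (all-MIBC comparison):")
print(as.data.frame(tbl[grepl("all", tbl$comparison),
                        c("cohort", "mirna", "p", "auc", "significant")]),
      digits = 3)

kw <- lapply(targets, function(m) {
  g <- split(expr[[m]], expr$group)
  r <- kruskal_wallis(list(g$pTa_lg, g$pT1_hg, g$MIBC))
  tibble::tibble(mirna = m, H = r$H, p = r$p)
})
kw <- dplyr::bind_rows(kw)
readr::write_csv(kw, "results/threegroup_kruskal.csv")

rho <- feature_correlation(expr[["miR-146b-5p"]], expr[["miR-155-5p"]])
jsonlite::write_json(
  list(spearman_146b_155 = rho),
  "results/feature_correlation.json", auto_unbox = TRUE, digits = NA)
message(sprintf("Spearman correlation miR-146b-5p ~ miR-155-5p: %.2f", rho))
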