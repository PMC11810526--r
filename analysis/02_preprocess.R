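#!/usr/bin/env Rscript
# Stage 2 — preprocess: aggregate triplicates (mean, spread-QC), apply the
# strict Ct < 35 expression filter, pick the reference assay (stable and not
# group-dependent), and normalize by the comparative-Ct method. Two
# expression tables are written: relative expression 2^-dCt for the
# biomarker statistics, and -dCt (log2 relative) for the classifiers.

library(mirmibc)

records <- read_assay_records("results/raw_records.csv")
candidates <- c("miR-361-5p", "miR-191-5p", "RNU48")
targets <- c("miR-138-5p", "miR-146b-5p", "miR-155-5p", "miR-200a-3p")

prep <- preprocess_records(records, candidates = candidates, assays = targets)
readr::write_csv(prep$reference_report, "results/reference_report.csv")
readr::write_csv(prep$expression, "results/expression.csv")

model_expr <- preprocess_records(records, reference = prep$reference,
                                 assays = targets,
                                 scale = "neg_delta_ct")$expression
readr::write_csv(model_expr, "results/expression_model.csv")

message("Reference assay selected: ", prep$reference)
print(prep$reference_report)
n_flag <- sum(prep$ct_table$qc_flag)
n_miss <- sum(is.na(prep$ct_table$ct[prep$ct_table$assay %in% targets]))
message(n_flag, " (sample, assay) pairs flagged for replicate spread > 1 cycle; ",
        n_miss, " target measurements below the expression filter (Ct >= 35).")
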