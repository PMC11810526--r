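#!/usr/bin/env Rscript
# Stage 1 — simulate the study: two qRT-PCR cohorts of pTa lg / MIBC tumours
# (n = 66 and n = 183) plus 120 pT1 hg TURB samples attached to cohort 2,
# with triplicate Ct records for the four target miRNAs and three candidate
# reference assays, and IHC marker panels for the MIBC samples.

library(mirmibc)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed)
sim <- generate_cohorts(cfg)
panels <- generate_marker_panels(cfg, sim$truth)

write_assay_records(sim$records, "results/raw_records.csv")
readr::write_csv(sim$truth, "results/latent_truth.csv")
readr::write_csv(panels, "results/marker_panels.csv")

tab <- table(sim$truth$cohort, sim$truth$group)
message("Simulated sample roster (seed ", seed, "):")
print(tab)
message(nrow(sim$records), " raw assay records (",
        length(unique(sim$records$assay)), " assays x ",
        nrow(sim$truth), " samples), ", nrow(panels),
        " MIBC marker panels.")
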