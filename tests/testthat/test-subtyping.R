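# small helper: panels with a known subtype structure straight from the
# generator's truth table
subtyped_panels <- function(seed, n_mibc = 40, ...) {
  cohorts <- list(c1 = c(pTa_lg = 5, pT1_hg = 0, MIBC = n_mibc),
                  c2 = c(pTa_lg = 5, pT1_hg = 0, MIBC = 5))
  cfg <- generator_config(seed = seed, cohorts = cohorts, ...)
  sim <- generate_cohorts(cfg)
  truth <- sim$truth[sim$truth$cohort == "c1" & sim$truth$group == "MIBC", ]
  panels <- generate_marker_panels(cfg, truth)
  list(panels = panels, truth = truth, cfg = cfg, sim = sim)
}

test_that("Z-scoring uses the sample-sd convention and flags constants", {
  m <- rbind(c(CK5 = 0, CK14 = 3), c(CK5 = 12, CK14 = 3))
  z <- zscore_markers(m)
  expect_equal(z[, "CK5"], c(-1, 1) / sqrt(2))
  expect_equal(z[, "CK14"], c(0, 0))
  expect_equal(attr(z, "flagged_constant"), "CK14")
  expect_error(zscore_markers(m[1, , drop = FALSE]),
               class = "mirmibc_subtype_error")
  # every standardized column is centred
  s <- subtyped_panels(1)
  zz <- zscore_markers(s$panels)
  expect_equal(unname(colMeans(zz)), rep(0, ncol(zz)), tolerance = 1e-12)
})

test_that("Ward two-cluster labels recover well-separated synthetic subtypes", {
  s <- subtyped_panels(seed = 17, n_mibc = 40)
  z <- zscore_markers(s$panels)
  labels <- ward_subtype(z)
  expect_equal(as.character(labels), s$truth$subtype)
  # merge heights non-decreasing along the agglomeration
  expect_true(all(diff(attr(labels, "hclust")$height) >= -1e-10))
})

test_that("labels are invariant to row and column permutations", {
  s <- subtyped_panels(seed = 23, n_mibc = 30)
  z <- zscore_markers(s$panels)
  base <- ward_subtype(z)
  perm <- withr::with_seed(1, sample(nrow(z)))
  zp <- z[perm, rev(colnames(z))]
  permuted <- ward_subtype(zp)
  expect_equal(as.character(permuted), as.character(base)[perm])
})

test_that("duplicated tumours get identical labels; n = 2 splits one per cluster", {
  s <- subtyped_panels(seed = 31, n_mibc = 20)
  z <- zscore_markers(s$panels)
  zdup <- rbind(z, z)
  rownames(zdup) <- c(rownames(z), paste0(rownames(z), "_dup"))
  labs <- ward_subtype(zdup)
  expect_equal(as.character(labs[seq_len(nrow(z))]),
               as.character(labs[nrow(z) + seq_len(nrow(z))]))

  two <- zscore_markers(rbind(c(CK5 = 12, CK14 = 11, CK20 = 1, GATA3 = 2,
                                FOXA1 = 1, CD44 = 10, UPK2 = 0),
                              c(CK5 = 1, CK14 = 0, CK20 = 10, GATA3 = 11,
                                FOXA1 = 10, CD44 = 2, UPK2 = 9)))
  lab2 <- ward_subtype(two)
  expect_setequal(as.character(lab2), c("basal", "luminal"))
  expect_equal(as.character(lab2)[1], "basal") # CK5/CK14/CD44-high tumour
})

test_that("subtype recovery is exact across 20 seeds at >= 3 sd separation", {
  # default marker means are >= 3 marker-noise sds apart between subtypes
  for (seed in 1:20) {
    s <- subtyped_panels(seed = 100 + seed, n_mibc = 30)
    labels <- ward_subtype(zscore_markers(s$panels))
    expect_equal(as.character(labels), s$truth$subtype,
                 info = paste("seed", seed))
  }
})

test_that("subtype-stratified miRNA comparisons detect the configured shifts", {
  # 2-cycle subtype offsets at n = 60: comfortably powered for the rank test
  s <- subtyped_panels(
    seed = 47, n_mibc = 60,
    subtype_delta_ct_shift = c("miR-138-5p" = 0, "miR-146b-5p" = -2,
                               "miR-155-5p" = -2, "miR-200a-3p" = 2))
  expr <- preprocess_records(s$sim$records, reference = "miR-361-5p",
                             assays = s$cfg$mirnas)$expression
  expr <- expr[expr$sample_id %in% s$truth$sample_id, ]
  labels <- stats::setNames(s$truth$subtype, s$truth$sample_id)
  cmp <- compare_by_subtype(expr, labels)
  # generator: basal has lower delta-Ct (higher expression) for miR-146b/155,
  # higher delta-Ct for miR-200a, no shift for miR-138
  expect_equal(cmp$direction[cmp$mirna == "miR-146b-5p"], "basal-high")
  expect_true(cmp$p[cmp$mirna == "miR-146b-5p"] < 0.05)
  expect_equal(cmp$direction[cmp$mirna == "miR-155-5p"], "basal-high")
  expect_equal(cmp$direction[cmp$mirna == "miR-200a-3p"], "basal-low")
  expect_true(cmp$p[cmp$mirna == "miR-200a-3p"] < 0.05)
  expect_true(cmp$p[cmp$mirna == "miR-138-5p"] > 0.05)

  # three-way comparison against a reference group adds Kruskal-Wallis
  pta <- preprocess_records(s$sim$records, reference = "miR-361-5p",
                            assays = s$cfg$mirnas)$expression
  pta <- pta[pta$group == "pTa_lg", ]
  cmp3 <- compare_by_subtype(expr, labels, reference_expr = pta)
  expect_true(all(c("H_threeway", "p_threeway") %in% names(cmp3)))

  # degenerate and error paths
  same <- expr
  for (m in s$cfg$mirnas) same[[m]] <- 1
  cmp_same <- compare_by_subtype(same, labels)
  expect_true(all(cmp_same$p == 1))
  expect_true(all(cmp_same$direction == "none"))
  expect_error(compare_by_subtype(expr, rep("basal", nrow(expr))),
               class = "mirmibc_subtype_error")
})
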