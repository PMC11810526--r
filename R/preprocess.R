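#' Aggregate qRT-PCR triplicates to one Ct per (sample, assay)
#'
#' The aggregate is the arithmetic mean of the available replicates (a single
#' replicate stands as-is). Replicates spreading more than `max_spread`
#' cycles are flagged in a QC column but never auto-removed: without a stated
#' removal rule, flag-and-keep is the reproducible choice.
#'
#' @param records Raw assay records (see [validate_records()]).
#' @param max_spread QC threshold on the replicate range, cycles.
#' @return A Ct table: `sample_id`, `cohort`, `group`, `source`, `assay`,
#'   `ct` (mean of replicates), `qc_spread` (range), `qc_flag`.
#' @export
aggregate_triplicates <- function(records, max_spread = 1.0) {
  records <- validate_records(records)
  reps <- as.matrix(records[c("ct_rep1", "ct_rep2", "ct_rep3")])
  ct <- rowMeans(reps, na.rm = TRUE)
  spread <- apply(reps, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) NA_real_ else max(r) - min(r)
  })
  tibble::tibble(
    sample_id = records$sample_id, cohort = records$cohort,
    group = records$group, source = records$source, assay = records$assay,
    ct = ct, qc_spread = spread,
    qc_flag = !is.na(spread) & spread > max_spread
  )
}

#' Apply the qRT-PCR expression filter
#'
#' Marks assays with Ct at or above the threshold as not expressed (Ct set to
#' missing). The inequality is strict: only Ct < `threshold` counts as
#' expressed, so a Ct of exactly 35 is filtered out. Idempotent.
#'
#' @param ct_table Aggregated Ct table from [aggregate_triplicates()].
#' @param threshold Expression threshold in cycles (default 35).
#' @return The Ct table with non-expressed cells set to `NA` and a logical
#'   `expressed` column.
#' @export
filter_expressed <- function(ct_table, threshold = 35) {
  expressed <- !is.na(ct_table$ct) & ct_table$ct < threshold
  ct_table$ct[!expressed] <- NA_real_
  ct_table$expressed <- expressed
  ct_table
}

#' Select the reference assay for normalization
#'
#' Screens candidate endogenous controls: a candidate is eligible when its
#' two-sided Mann--Whitney p-value between the two classification groups
#' exceeds `alpha` (no group difference); among eligible candidates the one
#' with the smallest Ct variance across all samples wins.
#'
#' @param ct_table Aggregated Ct table.
#' @param candidates Character vector of candidate assay names.
#' @param group_pair The two groups that must not differ (default
#'   pTa lg vs MIBC).
#' @param alpha Screen level (default 0.05).
#' @return List with `reference` (chosen assay) and `report` (tibble of
#'   per-candidate variance, p-value and eligibility).
#' @export
select_reference <- function(ct_table, candidates,
                             group_pair = c("pTa_lg", "MIBC"), alpha = 0.05) {
  stopifnot(length(candidates) >= 1)
  report <- purrr::map_dfr(candidates, function(a) {
    sub <- ct_table[ct_table$assay == a & !is.na(ct_table$ct), ]
    x <- sub$ct[sub$group == group_pair[1]]
    y <- sub$ct[sub$group == group_pair[2]]
    if (length(x) == 0 || length(y) == 0) {
      rlang::abort(paste0("Candidate '", a, "': one of the groups is empty."),
                   class = "mirmibc_config_error")
    }
    mw <- mann_whitney(x, y)
    tibble::tibble(assay = a, variance = stats::var(sub$ct), p_group = mw$p)
  })
  report$eligible <- report$p_group > alpha
  if (!any(report$eligible)) {
    rlang::abort(paste0(
      "No candidate reference passed the group-difference screen (all p <= ",
      alpha, "); choose a reference manually."),
      class = "mirmibc_reference_error")
  }
  elig <- report[report$eligible, ]
  list(reference = elig$assay[which.min(elig$variance)], report = report)
}

#' Normalize T values against a reference assay
#'
#' Comparative-Ct normalization: relative expression
#' \eqn{2^{-(Ct_{target} - Ct_{ref})}} (the `"relative"` scale), or
#' \eqn{-\Delta Ct} directly (the `"neg_delta_ct"` scale, i.e. log2 relative
#' expression). Missing target cells (not expressed) stay missing; samples
#' missing the reference are dropped with a message stating the count.
#'
#' @param ct_table Filtered Ct table from [filter_expressed()].
#' @param reference Reference assay name.
#' @param scale Output scale, `"relative"` (default) or `"neg_delta_ct"`.
#' @param assays Target assays to keep as columns; default all assays except
#'   the reference.
#' @return An expression table: one row per sample with metadata columns
#'   (`sample_id`, `cohort`, `group`, `source`) followed by one column per
#'   assay. Attributes `reference` and `scale` record the normalization.
#' @export
normalize_expression <- function(ct_table, reference,
                                 scale = c("relative", "neg_delta_ct"),
                                 assays = NULL) {
  scale <- match.arg(scale)
  if (!reference %in% ct_table$assay) {
    rlang::abort(paste0("Reference assay '", reference, "' not in the Ct table."),
                 class = "mirmibc_config_error")
  }
  if (is.null(assays)) assays <- setdiff(unique(ct_table$assay), reference)
  wide <- tidyr::pivot_wider(
    ct_table[c("sample_id", "cohort", "group", "source", "assay", "ct")],
    names_from = "assay", values_from = "ct")
  ref_ct <- wide[[reference]]
  n_drop <- sum(is.na(ref_ct))
  if (n_drop == nrow(wide)) {
    rlang::abort("Reference assay missing (not expressed) for every sample.",
                 class = "mirmibc_reference_error")
  }
  if (n_drop > 0) {
    message(n_drop, " sample(s) dropped: reference assay not expressed.")
    wide <- wide[!is.na(ref_ct), ]
    ref_ct <- wide[[reference]]
  }
  out <- wide[c("sample_id", "cohort", "group", "source")]
  for (a in assays) {
    ndct <- -(wide[[a]] - ref_ct)
    out[[a]] <- if (scale == "relative") 2^ndct else ndct
  }
  attr(out, "reference") <- reference
  attr(out, "scale") <- scale
  out
}

#' One-call preprocessing: records to expression table
#'
#' Convenience wrapper chaining [aggregate_triplicates()],
#' [filter_expressed()], optional [select_reference()] and
#' [normalize_expression()].
#'
#' @param records Raw assay records.
#' @param reference Reference assay name, or `NULL` to select one from
#'   `candidates`.
#' @param candidates Candidate references when `reference` is `NULL`.
#' @param ct_threshold Expression filter threshold, cycles.
#' @param max_spread Triplicate QC threshold, cycles.
#' @param scale Expression scale, see [normalize_expression()].
#' @param assays Target assays to keep, see [normalize_expression()].
#' @return List with `expression` (the expression table), `reference`,
#'   `reference_report` (`NULL` when the reference was given) and `ct_table`.
#' @export
preprocess_records <- function(records, reference = NULL, candidates = NULL,
                               ct_threshold = 35, max_spread = 1.0,
                               scale = "relative", assays = NULL) {
  ct <- aggregate_triplicates(records, max_spread = max_spread)
  ct <- filter_expressed(ct, threshold = ct_threshold)
  ref_report <- NULL
  if (is.null(reference)) {
    sel <- select_reference(ct, candidates)
    reference <- sel$reference
    ref_report <- sel$report
  }
  if (is.null(assays)) {
    assays <- setdiff(unique(ct$assay), c(reference, candidates))
  }
  expr <- normalize_expression(ct, reference, scale = scale, assays = assays)
  list(expression = expr, reference = reference,
       reference_report = ref_report, ct_table = ct)
}
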