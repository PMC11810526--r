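ihc_markers <- function() c("CK5", "CK14", "CK20", "GATA3", "FOXA1", "CD44", "UPK2")
basal_markers <- function() c("CK5", "CK14", "CD44")

#' Read an IHC marker-panel table
#'
#' CSV with a `tumour_id` column plus the seven marker IRS columns
#' (integers 0--12). Tumours with a missing marker or an out-of-range score
#' are flagged in an `incomplete` column rather than dropped.
#'
#' @param path CSV path.
#' @return Tibble with `tumour_id`, seven marker columns and `incomplete`.
#' @export
read_marker_panels <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(c("tumour_id", ihc_markers()), names(tbl))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Marker panel missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "mirmibc_schema_error")
  }
  m <- as.matrix(tbl[ihc_markers()])
  tbl$incomplete <- apply(m, 1, function(r) any(is.na(r) | r < 0 | r > 12))
  tbl
}

#' Z-score-normalize an IHC marker matrix
#'
#' Standardizes each marker across tumours: (x - mean) / sd, with the
#' sample-sd (n - 1) convention. A zero-variance marker becomes a column of
#' zeros and is recorded in the `flagged_constant` attribute.
#'
#' @param panels Data frame with `tumour_id` and the seven marker columns,
#'   or a plain numeric matrix of marker scores.
#' @return Numeric matrix of Z scores (rows = tumours, named by tumour id
#'   when available), with attribute `flagged_constant`.
#' @export
zscore_markers <- function(panels) {
  if (is.data.frame(panels)) {
    ids <- if ("tumour_id" %in% names(panels)) panels$tumour_id else NULL
    m <- as.matrix(panels[intersect(ihc_markers(), names(panels))])
    rownames(m) <- ids
  } else {
    m <- as.matrix(panels)
  }
  if (nrow(m) < 2) {
    rlang::abort("Z-scoring needs at least two tumours.",
                 class = "mirmibc_subtype_error")
  }
  sds <- apply(m, 2, stats::sd)
  z <- scale(m) # sample-sd convention
  constant <- which(sds == 0)
  if (length(constant) > 0) z[, constant] <- 0
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "flagged_constant") <- colnames(m)[constant]
  z
}

#' Luminal/basal subtyping by Ward clustering
#'
#' Agglomerative Ward-linkage clustering (Euclidean distance on the
#' Z-scored marker matrix) cut into two clusters. The cluster with the
#' larger mean Z score over the basal markers CK5, CK14 and CD44 is
#' labelled `basal`, the other `luminal` — the taxonomy-standard direction.
#'
#' @param z Standardized marker matrix from [zscore_markers()].
#' @return Factor of labels (`luminal`, `basal`), named by tumour id when
#'   available; the dendrogram is attached as attribute `hclust`.
#' @export
ward_subtype <- function(z) {
  if (nrow(z) < 2) {
    rlang::abort("Clustering needs at least two tumours.",
                 class = "mirmibc_subtype_error")
  }
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  bm <- intersect(basal_markers(), colnames(z))
  mean_basal <- vapply(1:2, function(g) {
    mean(z[cl == g, bm, drop = FALSE])
  }, numeric(1))
  basal_cluster <- which.max(mean_basal)
  labels <- factor(ifelse(cl == basal_cluster, "basal", "luminal"),
                   levels = c("luminal", "basal"))
  names(labels) <- rownames(z)
  attr(labels, "hclust") <- hc
  labels
}

#' Compare miRNA expression between molecular subtypes
#'
#' Per-miRNA Mann--Whitney test between basal and luminal tumours with the
#' median direction (`basal-high`, `basal-low` or `none`). When a reference
#' group (e.g. pTa lg expression) is supplied, a three-way Kruskal--Wallis
#' test across luminal / basal / reference is added.
#'
#' @param expr Expression table restricted to the subtyped samples (must
#'   contain `sample_id` and the miRNA columns).
#' @param labels Factor/character of subtype labels named by `sample_id`, or
#'   aligned with the rows of `expr`.
#' @param mirnas miRNA columns to test; default all non-metadata columns.
#' @param reference_expr Optional expression table of a comparison group for
#'   the three-way test.
#' @param alpha Significance threshold for the `significant` flag.
#' @return Tibble with one row per miRNA: medians, `U`, `p`, `direction`,
#'   optional `H_threeway`, `p_threeway`.
#' @export
compare_by_subtype <- function(expr, labels, mirnas = NULL,
                               reference_expr = NULL, alpha = 0.05) {
  meta <- c("sample_id", "cohort", "group", "source")
  if (is.null(mirnas)) mirnas <- setdiff(names(expr), meta)
  lab <- if (!is.null(names(labels))) {
    as.character(labels[expr$sample_id])
  } else {
    as.character(labels)
  }
  if (length(lab) != nrow(expr) || anyNA(lab)) {
    rlang::abort("Subtype labels do not align with the expression table.",
                 class = "mirmibc_subtype_error")
  }
  if (!all(c("luminal", "basal") %in% lab)) {
    rlang::abort("Both subtypes must be present.",
                 class = "mirmibc_subtype_error")
  }
  purrr::map_dfr(mirnas, function(m) {
    b <- expr[[m]][lab == "basal"]
    l <- expr[[m]][lab == "luminal"]
    mw <- mann_whitney(l, b)
    med_b <- stats::median(b, na.rm = TRUE)
    med_l <- stats::median(l, na.rm = TRUE)
    direction <- if (mw$degenerate || med_b == med_l) {
      "none"
    } else if (med_b > med_l) {
      "basal-high"
    } else {
      "basal-low"
    }
    row <- tibble::tibble(
      mirna = m, median_luminal = med_l, median_basal = med_b,
      U = mw$U, p = mw$p, direction = direction, significant = mw$p < alpha
    )
    if (!is.null(reference_expr)) {
      kw <- kruskal_wallis(list(
        luminal = l[!is.na(l)], basal = b[!is.na(b)],
        reference = reference_expr[[m]][!is.na(reference_expr[[m]])]))
      row$H_threeway <- kw$H
      row$p_threeway <- kw$p
    }
    row
  })
}
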