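#' Mann--Whitney U test
#'
#' Rank-sum test with mid-ranks for ties. The p-value is exact (full
#' enumeration of label assignments) when the combined sample size is at most
#' 12 and there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used. Identical degenerate samples (every value
#' equal) return U = n1*n2/2 and p = 1 with a flag.
#'
#' @param x,y Numeric samples (non-empty; NAs dropped).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List: `U` (statistic for `x`), `p`, `exact` (logical), and
#'   `degenerate`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("Both samples must be non-empty.", class = "mirmibc_stat_error")
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1) {
    return(list(U = u, p = 1, exact = FALSE, degenerate = TRUE))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2) <= 12 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE)$p.value)
  list(U = u, p = min(p, 1), exact = exact, degenerate = FALSE)
}

#' Kruskal--Wallis test for three or more groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom. With only two groups the Mann--Whitney test is
#' the appropriate tool and an error is raised. A fully degenerate input
#' (every observation equal) returns H = 0 and p = 1.
#'
#' @param groups List of at least three numeric samples.
#' @return List: `H`, `p`, `df`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    rlang::abort("Need >= 3 groups; use mann_whitney() for two.",
                 class = "mirmibc_stat_error")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0)) {
    rlang::abort("Every group must be non-empty.", class = "mirmibc_stat_error")
  }
  all_v <- unlist(groups)
  if (length(unique(all_v)) == 1) {
    return(list(H = 0, p = 1, df = length(groups) - 1, degenerate = TRUE))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' ROC curve and AUC by pairwise concordance
#'
#' The AUC is the probability that a random positive scores above a random
#' negative, ties counting 1/2 — computed from rank sums, which is exactly
#' the Mann--Whitney U divided by n1*n0. Operating points enumerate all
#' distinct score thresholds (prediction positive when score >= threshold),
#' forming a monotone staircase from sensitivity 0 / specificity 1 to
#' sensitivity 1 / specificity 0.
#'
#' @param scores Numeric per-sample scores (higher = more positive-like).
#' @param labels Binary labels (logical, or coercible factor with exactly two
#'   levels).
#' @param positive The label value treated as positive; default the first
#'   canonical class (`"MIBC"`) if present, else the larger factor level.
#' @return An object of class `roc_curve`: list with `points` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  ul <- unique(as.character(labels))
  if (length(ul) != 2) {
    rlang::abort("Both label classes must be present.",
                 class = "mirmibc_stat_error")
  }
  if (is.null(positive)) positive <- if ("MIBC" %in% ul) "MIBC" else ul[1]
  if (!positive %in% ul) {
    rlang::abort("`positive` is not one of the label values.",
                 class = "mirmibc_stat_error")
  }
  pos <- as.character(labels) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(pos & scores >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(!pos & scores < t) / n0, numeric(1))
  points <- tibble::tibble(
    threshold = c(Inf, thr, -Inf),
    sensitivity = c(0, sens, 1),
    specificity = c(1, spec, 0)
  )
  structure(list(points = points, auc = auc, n_pos = n1, n_neg = n0,
                 positive = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve: AUC =", format(x$auc, digits = 4),
      sprintf("(%d positive vs %d negative, positive = %s)\n",
              x$n_pos, x$n_neg, x$positive))
  invisible(x)
}

#' Correlation between two expression features
#'
#' Rank-based (Spearman) by default, matching the nonparametric framing of
#' the rest of the analysis; Pearson selectable. Requires at least three
#' complete pairs; zero variance in either vector yields `NA` with a warning.
#'
#' @param x,y Paired numeric vectors.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A single correlation value in \[-1, 1\] (or `NA`).
#' @export
feature_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    rlang::abort("Need >= 3 complete pairs.", class = "mirmibc_stat_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Zero variance in one of the vectors; correlation undefined.")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Per-miRNA biomarker statistics stratified by specimen source
#'
#' Reproduces the layout of the study's per-miRNA summary: for each cohort
#' and each comparison (pTa lg vs MIBC restricted to TURB MIBC samples, to
#' CYS MIBC samples, and to all MIBC samples), the group medians,
#' Mann--Whitney U and p, and the AUC of expression as a score for MIBC.
#'
#' @param expr Expression table from [normalize_expression()].
#' @param mirnas miRNA columns to test; default every non-metadata column.
#' @param alpha Significance threshold used for the `significant` flag
#'   (default 0.05, no multiplicity correction — single-marker screening is
#'   reported as-is, mirroring common qRT-PCR practice; interpret
#'   accordingly).
#' @return Tibble with one row per (cohort, comparison, miRNA).
#' @export
biomarker_table <- function(expr, mirnas = NULL, alpha = 0.05) {
  meta <- c("sample_id", "cohort", "group", "source")
  if (is.null(mirnas)) mirnas <- setdiff(names(expr), meta)
  comparisons <- c("TURB", "CYS", "all")
  purrr::map_dfr(unique(expr$cohort), function(co) {
    sub <- expr[expr$cohort == co, ]
    purrr::map_dfr(comparisons, function(cmp) {
      mibc <- sub[sub$group == "MIBC", ]
      if (cmp != "all") mibc <- mibc[mibc$source == cmp, ]
      pta <- sub[sub$group == "pTa_lg", ]
      if (nrow(mibc) == 0 || nrow(pta) == 0) return(NULL)
      purrr::map_dfr(mirnas, function(m) {
        x <- pta[[m]]; y <- mibc[[m]]
        mw <- mann_whitney(x[!is.na(x)], y[!is.na(y)])
        sc <- c(x, y)
        lb <- rep(c("pTa_lg", "MIBC"), c(length(x), length(y)))
        ok <- !is.na(sc)
        auc <- roc_auc(sc[ok], lb[ok], positive = "MIBC")$auc
        tibble::tibble(
          cohort = co, comparison = paste0("pTa_lg-MIBC (", cmp, ")"),
          mirna = m,
          median_pTa_lg = stats::median(x, na.rm = TRUE),
          median_MIBC = stats::median(y, na.rm = TRUE),
          U = mw$U, p = mw$p, auc = auc,
          significant = mw$p < alpha
        )
      })
    })
  })
}
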