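#' Canonical class labels
#'
#' The two classification targets in canonical order. The canonical order
#' (MIBC first) is the documented tie-break wherever two classes have exactly
#' equal predicted probability.
#'
#' @return Character vector `c("MIBC", "pTa_lg")`.
#' @export
mibc_classes <- function() c("MIBC", "pTa_lg")

#' Tumour group labels
#'
#' @return Character vector of the three histology groups.
#' @export
mibc_groups <- function() c("pTa_lg", "pT1_hg", "MIBC")

#' Specimen source labels
#' @return Character vector `c("TURB", "CYS")`.
#' @export
mibc_sources <- function() c("TURB", "CYS")

# coerce to the canonical two-class factor, erroring on anything else
as_class_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), mibc_classes())
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Labels outside {MIBC, pTa_lg}: ", paste(bad, collapse = ", ")),
      class = "mirmibc_schema_error"
    )
  }
  factor(x, levels = mibc_classes())
}

# stable check that a matrix is symmetric positive semidefinite
is_psd <- function(m, tol = 1e-8) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(abs(ev), 1))
}

# derive a stream of child seeds from one top-level seed, staying < 2^31
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000 + offset) %% .Machine$integer.max)
}
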