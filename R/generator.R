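#' Default immunoreactive-score means per subtype and marker
#'
#' Mean IRS (0--12 scale) for the seven IHC markers used for luminal/basal
#' subtyping. Basal tumours score high on CK5/CK14/CD44, luminal tumours on
#' CK20/GATA3/FOXA1/UPK2, following the standard bladder-cancer taxonomy
#' direction.
#'
#' @return A 2 x 7 numeric matrix with rows `luminal`, `basal`.
#' @export
default_marker_means <- function() {
  rbind(
    luminal = c(CK5 = 2, CK14 = 1, CK20 = 9, GATA3 = 10, FOXA1 = 9, CD44 = 2, UPK2 = 8),
    basal   = c(CK5 = 9, CK14 = 8, CK20 = 2, GATA3 = 3, FOXA1 = 3, CD44 = 9, UPK2 = 1)
  )
}

default_mirnas <- function() {
  c("miR-138-5p", "miR-146b-5p", "miR-155-5p", "miR-200a-3p")
}

default_delta_ct_means <- function() {
  m <- rbind(
    pTa_lg = c(1.0, 3.0, 4.0, 0.0),
    MIBC   = c(1.5, 0.0, 1.5, 0.5)
  )
  colnames(m) <- default_mirnas()
  m
}

default_delta_ct_cov <- function(sd = 1.5) {
  mirnas <- default_mirnas()
  r <- matrix(0.2, 4, 4, dimnames = list(mirnas, mirnas))
  diag(r) <- 1
  # miR-146b-5p and miR-155-5p co-regulated (correlation ~0.6)
  r["miR-146b-5p", "miR-155-5p"] <- r["miR-155-5p", "miR-146b-5p"] <- 0.6
  sd^2 * r
}

#' Configuration for the synthetic qRT-PCR cohort generator
#'
#' Builds a validated configuration describing two (or more) cohorts of
#' bladder-tumour samples assayed by triplicate qRT-PCR on a small miRNA
#' panel. Expression is modelled on the \eqn{\Delta Ct} (log2) scale: each
#' sample draws a reference-assay Ct and a group-specific multivariate-normal
#' \eqn{\Delta Ct} vector, giving target Ct = reference Ct + \eqn{\Delta Ct};
#' technical triplicates add independent Gaussian noise. pT1 high-grade
#' samples are a two-component mixture of the pTa-like and MIBC-like
#' distributions. MIBC samples carry a latent luminal/basal subtype that
#' shifts the miRNA means and drives a synthetic IHC marker panel.
#'
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical cohorts.
#' @param cohorts Named list: cohort id -> named integer vector of per-group
#'   sample counts over `c(pTa_lg, pT1_hg, MIBC)`. Defaults give the study
#'   layout: cohort sizes 66 and 183 (pTa lg + MIBC) plus 120 pT1 hg TURB
#'   samples in cohort 2.
#' @param mirnas Character vector of target miRNA assay names.
#' @param delta_ct_means Matrix (rows `pTa_lg`, `MIBC`; columns miRNAs) of
#'   mean \eqn{\Delta Ct} in cycles.
#' @param delta_ct_cov Either one covariance matrix (cycles^2) shared by both
#'   phenotypes or a named list with entries `pTa_lg` and `MIBC`.
#' @param source_fractions Named vector, per group, of the fraction of TURB
#'   specimens (remainder CYS). The pTa lg group contains no CYS samples.
#' @param reference_assays Data frame of candidate endogenous controls with
#'   columns `assay`, `ct_mean`, `ct_sd`, `mibc_shift` (cycles added for MIBC
#'   samples; a stable reference has shift 0). The first row is the assay
#'   whose per-sample Ct anchors the targets.
#' @param replicate_sd Technical triplicate noise sd, cycles.
#' @param pt1_mibc_mixture_weight Probability that a pT1 hg sample is drawn
#'   from the MIBC-like component.
#' @param dropout_rate Per (sample, target-assay) probability of
#'   non-expression.
#' @param dropout_ct_shift Cycles added to a non-expressed assay, pushing it
#'   above the Ct 35 expression filter rather than deleting the record.
#' @param subtype_fraction_basal Fraction of MIBC samples with the basal
#'   subtype.
#' @param subtype_delta_ct_shift Named vector of cycles added to the
#'   \eqn{\Delta Ct} mean of basal MIBC samples (negative = higher
#'   expression in basal).
#' @param marker_irs_means Matrix of per-subtype per-marker IRS means, see
#'   [default_marker_means()].
#' @param marker_irs_sd IRS noise sd before rounding/clipping to 0--12.
#'
#' @return A validated `generator_config` object (list).
#' @export
generator_config <- function(
    seed = 1L,
    cohorts = list(
      cohort1 = c(pTa_lg = 30, pT1_hg = 0,   MIBC = 36),
      cohort2 = c(pTa_lg = 83, pT1_hg = 120, MIBC = 100)
    ),
    mirnas = default_mirnas(),
    delta_ct_means = default_delta_ct_means(),
    delta_ct_cov = default_delta_ct_cov(),
    source_fractions = c(pTa_lg = 1, pT1_hg = 1, MIBC = 0.35),
    reference_assays = data.frame(
      assay = c("miR-361-5p", "miR-191-5p", "RNU48"),
      ct_mean = c(28, 26, 24),
      ct_sd = c(0.5, 1.2, 0.8),
      mibc_shift = c(0, 0, 0.8)
    ),
    replicate_sd = 0.15,
    pt1_mibc_mixture_weight = 0.3,
    dropout_rate = 0.02,
    dropout_ct_shift = 12,
    subtype_fraction_basal = 0.45,
    subtype_delta_ct_shift = c(
      "miR-138-5p" = 0, "miR-146b-5p" = -1, "miR-155-5p" = -1, "miR-200a-3p" = 1
    ),
    marker_irs_means = default_marker_means(),
    marker_irs_sd = 1.5) {
  if (!is.list(delta_ct_cov)) {
    delta_ct_cov <- list(pTa_lg = delta_ct_cov, MIBC = delta_ct_cov)
  }
  cfg <- structure(
    list(
      seed = as.integer(seed), cohorts = cohorts, mirnas = mirnas,
      delta_ct_means = delta_ct_means, delta_ct_cov = delta_ct_cov,
      source_fractions = source_fractions, reference_assays = reference_assays,
      replicate_sd = replicate_sd,
      pt1_mibc_mixture_weight = pt1_mibc_mixture_weight,
      dropout_rate = dropout_rate, dropout_ct_shift = dropout_ct_shift,
      subtype_fraction_basal = subtype_fraction_basal,
      subtype_delta_ct_shift = subtype_delta_ct_shift,
      marker_irs_means = marker_irs_means, marker_irs_sd = marker_irs_sd
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks positive-semidefinite covariances, fractions/weights in \[0, 1\],
#' non-negative integer group counts with both classification groups present,
#' and aligned miRNA names. Called by [generator_config()]; exported so
#' configurations modified by hand can be re-checked.
#'
#' @param cfg A `generator_config`.
#' @return `cfg`, invisibly, or an error describing the violation.
#' @export
validate_generator_config <- function(cfg) {
  abort_cfg <- function(msg) rlang::abort(msg, class = "mirmibc_config_error")
  for (id in names(cfg$cohorts)) {
    n <- cfg$cohorts[[id]]
    if (!all(mibc_groups() %in% names(n))) {
      abort_cfg(paste0("Cohort '", id, "' must name counts for all of: ",
                       paste(mibc_groups(), collapse = ", ")))
    }
    if (any(n < 0) || any(n != round(n))) {
      abort_cfg(paste0("Cohort '", id, "' has negative or non-integer counts."))
    }
    if (n[["pTa_lg"]] < 1 || n[["MIBC"]] < 1) {
      abort_cfg(paste0("Cohort '", id, "' has a zero-size classification group; ",
                       "pTa_lg and MIBC each need at least one sample."))
    }
  }
  for (g in c("pTa_lg", "MIBC")) {
    cv <- cfg$delta_ct_cov[[g]]
    if (is.null(cv) || !is_psd(cv)) {
      abort_cfg(paste0("delta_ct_cov for group '", g,
                       "' is missing or not symmetric positive semidefinite."))
    }
    if (nrow(cv) != length(cfg$mirnas)) {
      abort_cfg("delta_ct_cov dimension does not match the miRNA panel.")
    }
  }
  fr <- c(cfg$source_fractions, cfg$pt1_mibc_mixture_weight,
          cfg$dropout_rate, cfg$subtype_fraction_basal)
  if (any(fr < 0 | fr > 1)) abort_cfg("All fractions and weights must lie in [0, 1].")
  if (cfg$replicate_sd < 0) abort_cfg("replicate_sd must be >= 0.")
  if (!setequal(colnames(cfg$delta_ct_means), cfg$mirnas)) {
    abort_cfg("delta_ct_means columns must match the miRNA panel.")
  }
  invisible(cfg)
}

#' Generate synthetic qRT-PCR cohorts
#'
#' Draws the sample roster, latent components and subtypes, per-sample
#' \eqn{\Delta Ct} vectors, reference-assay Ts, dropout events and technical
#' triplicates described by a [generator_config()]. Latent truth is returned
#' in a separate table and never leaks into the analysis-facing records.
#'
#' @param cfg A validated `generator_config`.
#' @return A list with
#'   \describe{
#'     \item{records}{tibble of raw assay records, one row per
#'       (sample, assay): `sample_id`, `cohort`, `group`, `source`, `assay`,
#'       `ct_rep1`, `ct_rep2`, `ct_rep3`.}
#'     \item{truth}{tibble of latent truth: generating `component`
#'       (`pTa-like` / `MIBC-like`), `subtype` (MIBC-like draws only), the true
#'       \eqn{\Delta Ct} per miRNA (`dct_*`) and per-assay dropout flags.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohorts <- function(cfg) {
  validate_generator_config(cfg)
  withr::with_seed(cfg$seed, {
    roster <- purrr::imap_dfr(cfg$cohorts, function(counts, cohort_id) {
      purrr::map_dfr(mibc_groups(), function(g) {
        n <- counts[[g]]
        if (n == 0) return(NULL)
        tibble::tibble(cohort = cohort_id, group = g, idx = seq_len(n))
      })
    })
    n_all <- nrow(roster)
    roster$sample_id <- sprintf("%s_S%04d", roster$cohort, stats::ave(
      rep(1, n_all), roster$cohort, FUN = cumsum))

    # latent generating component: pT1 hg is a mixture of the two phenotypes
    comp <- ifelse(roster$group == "MIBC", "MIBC-like",
                   ifelse(roster$group == "pTa_lg", "pTa-like", NA))
    is_pt1 <- roster$group == "pT1_hg"
    comp[is_pt1] <- ifelse(
      stats::runif(sum(is_pt1)) < cfg$pt1_mibc_mixture_weight,
      "MIBC-like", "pTa-like")
    roster$component <- comp

    # latent subtype for every MIBC-like draw (so a pT1 hg sample from the
    # MIBC-like component follows the full MIBC mixture distribution)
    roster$subtype <- NA_character_
    is_mibc <- roster$component == "MIBC-like"
    roster$subtype[is_mibc] <- ifelse(
      stats::runif(sum(is_mibc)) < cfg$subtype_fraction_basal, "basal", "luminal")

    # specimen source per group
    roster$source <- ifelse(
      stats::runif(n_all) < cfg$source_fractions[roster$group], "TURB", "CYS")

    # per-sample delta-Ct draws, vectorized over the distinct mean vectors
    p <- length(cfg$mirnas)
    dct <- matrix(NA_real_, n_all, p, dimnames = list(NULL, cfg$mirnas))
    cells <- interaction(roster$component,
                         ifelse(is.na(roster$subtype), "none", roster$subtype),
                         drop = TRUE)
    for (cell in levels(cells)) {
      rows <- which(cells == cell)
      comp_g <- if (roster$component[rows[1]] == "MIBC-like") "MIBC" else "pTa_lg"
      mu <- cfg$delta_ct_means[comp_g, cfg$mirnas]
      if (!is.na(roster$subtype[rows[1]]) && roster$subtype[rows[1]] == "basal") {
        mu <- mu + cfg$subtype_delta_ct_shift[cfg$mirnas]
      }
      dct[rows, ] <- MASS::mvrnorm(length(rows), mu = mu,
                                   Sigma = cfg$delta_ct_cov[[comp_g]])
    }

    # reference assays: the first anchors the targets
    refs <- cfg$reference_assays
    ref_ct <- matrix(NA_real_, n_all, nrow(refs),
                     dimnames = list(NULL, refs$assay))
    for (j in seq_len(nrow(refs))) {
      shift <- ifelse(roster$group == "MIBC", refs$mibc_shift[j], 0)
      ref_ct[, j] <- stats::rnorm(n_all, refs$ct_mean[j] + shift, refs$ct_sd[j])
    }

    # target Ct = anchor reference Ct + delta-Ct (+ dropout shift)
    target_ct <- ref_ct[, 1] + dct
    dropout <- matrix(stats::runif(n_all * p) < cfg$dropout_rate, n_all, p,
                      dimnames = list(NULL, cfg$mirnas))
    target_ct <- target_ct + dropout * cfg$dropout_ct_shift

    ct_true <- cbind(target_ct, ref_ct)
    assays <- colnames(ct_true)
    long_n <- n_all * length(assays)
    reps <- matrix(stats::rnorm(3 * long_n, 0, cfg$replicate_sd), long_n, 3)
    ct_vec <- as.vector(ct_true)

    records <- tibble::tibble(
      sample_id = rep(roster$sample_id, times = length(assays)),
      cohort = rep(roster$cohort, times = length(assays)),
      group = rep(roster$group, times = length(assays)),
      source = rep(roster$source, times = length(assays)),
      assay = rep(assays, each = n_all),
      ct_rep1 = ct_vec + reps[, 1],
      ct_rep2 = ct_vec + reps[, 2],
      ct_rep3 = ct_vec + reps[, 3]
    )
    records <- dplyr::arrange(records, .data$sample_id, .data$assay)

    truth <- tibble::as_tibble(roster[c("sample_id", "cohort", "group",
                                        "source", "component", "subtype")])
    dct_tbl <- tibble::as_tibble(as.data.frame(dct))
    names(dct_tbl) <- paste0("dct_", cfg$mirnas)
    drop_tbl <- tibble::as_tibble(as.data.frame(dropout))
    names(drop_tbl) <- paste0("dropout_", cfg$mirnas)
    truth <- dplyr::bind_cols(truth, dct_tbl, drop_tbl)

    list(records = records, truth = truth, config = cfg)
  })
}

#' Generate synthetic IHC marker panels for MIBC samples
#'
#' For every MIBC sample in the latent truth table, draws the seven-marker
#' immunoreactive scores (IRS, 0--12) around the configured per-subtype
#' means, with Gaussian noise rounded and clipped to the integer IRS scale.
#'
#' @param cfg A `generator_config`.
#' @param truth Latent truth table from [generate_cohorts()].
#' @param seed Seed for the marker draws (default derived from the config
#'   seed).
#' @return Tibble: `tumour_id` plus one integer column per marker.
#' @export
generate_marker_panels <- function(cfg, truth, seed = child_seed(cfg$seed, 1)) {
  mibc <- truth[truth$group == "MIBC" & !is.na(truth$subtype), ]
  if (nrow(mibc) == 0) {
    rlang::abort("No MIBC samples with a latent subtype in the truth table.",
                 class = "mirmibc_config_error")
  }
  markers <- colnames(cfg$marker_irs_means)
  withr::with_seed(seed, {
    irs <- sapply(markers, function(mk) {
      mu <- cfg$marker_irs_means[mibc$subtype, mk]
      pmin(12L, pmax(0L, as.integer(round(
        stats::rnorm(nrow(mibc), mu, cfg$marker_irs_sd)))))
    })
    irs <- matrix(irs, nrow = nrow(mibc), dimnames = list(NULL, markers))
    dplyr::bind_cols(tibble::tibble(tumour_id = mibc$sample_id),
                     tibble::as_tibble(as.data.frame(irs)))
  })
}

#' Validate a raw assay-record table
#'
#' Fail-fast schema check for the CSV/TSV record layout: required columns,
#' group and source labels from their enumerations, positive Ct replicates.
#' Violations are reported with the offending row numbers.
#'
#' @param records Data frame of raw assay records.
#' @return `records` as a tibble, invisibly on success.
#' @export
validate_records <- function(records) {
  req <- c("sample_id", "cohort", "group", "source", "assay",
           "ct_rep1", "ct_rep2", "ct_rep3")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
                 class = "mirmibc_schema_error")
  }
  bad_group <- which(!records$group %in% mibc_groups())
  if (length(bad_group) > 0) {
    rlang::abort(
      paste0("Invalid group label(s) ",
             paste(unique(records$group[bad_group]), collapse = ", "),
             " at row(s) ", paste(utils::head(bad_group, 5), collapse = ", ")),
      class = "mirmibc_schema_error")
  }
  bad_source <- which(!records$source %in% mibc_sources())
  if (length(bad_source) > 0) {
    rlang::abort(paste0("Invalid source label at row(s) ",
                        paste(utils::head(bad_source, 5), collapse = ", ")),
                 class = "mirmibc_schema_error")
  }
  reps <- as.matrix(records[c("ct_rep1", "ct_rep2", "ct_rep3")])
  bad_ct <- which(apply(reps, 1, function(r) all(is.na(r)) || any(r <= 0, na.rm = TRUE)))
  if (length(bad_ct) > 0) {
    rlang::abort(paste0("Non-positive or fully missing Ct replicates at row(s) ",
                        paste(utils::head(bad_ct, 5), collapse = ", ")),
                 class = "mirmibc_schema_error")
  }
  invisible(tibble::as_tibble(records))
}

#' Read / write raw assay records
#'
#' CSV round-trip for the raw record schema (`sample_id`, `cohort`, `group`,
#' `source`, `assay`, `ct_rep1..3`); reading validates the schema.
#'
#' @param records Record tibble.
#' @param path File path (CSV).
#' @return `read_assay_records()` returns the validated tibble.
#' @export
write_assay_records <- function(records, path) {
  validate_records(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_assay_records
#' @export
read_assay_records <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  validate_records(rec)
  rec
}
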