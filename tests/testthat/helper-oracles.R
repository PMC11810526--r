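# Independent brute-force oracles used to pin the statistical machinery.
# These deliberately share no code with the package implementation.

# Exact two-sided Mann-Whitney p by full enumeration of label assignments:
# the probability, over all C(n1+n2, n1) relabelings, of a U at least as
# extreme (two-sided around the mean n1*n2/2) as the observed one.
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# AUC as explicit pairwise concordance (ties count 1/2).
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force KNN class probabilities: sort every training point by
# (distance, index) and count votes among the first k.
oracle_knn_proba <- function(train_x, train_y, k, query,
                             center, scl) {
  ts <- sweep(sweep(train_x, 2, center), 2, scl, "/")
  qs <- (query - center) / scl
  d <- sqrt(colSums((t(ts) - qs)^2))
  ord <- order(d, seq_along(d))
  nn_y <- train_y[ord[seq_len(k)]]
  c(MIBC = sum(nn_y == "MIBC") / k, pTa_lg = sum(nn_y == "pTa_lg") / k)
}

# A small two-cohort expression table with a clean class signal, built
# directly (no generator) for model-selection unit tests.
toy_expression <- function(seed = 1, n1 = 24, n2 = 36, shift = 3) {
  withr::with_seed(seed, {
    make_cohort <- function(id, n) {
      g <- rep(c("pTa_lg", "MIBC"), each = n / 2)
      tibble::tibble(
        sample_id = sprintf("%s_%03d", id, seq_len(n)),
        cohort = id, group = g,
        source = ifelse(g == "MIBC" & stats::runif(n) < 0.4, "CYS", "TURB"),
        mirA = stats::rnorm(n) + shift * (g == "MIBC"),
        mirB = stats::rnorm(n),
        mirC = stats::rnorm(n)
      )
    }
    dplyr::bind_rows(make_cohort("c1", n1), make_cohort("c2", n2))
  })
}
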