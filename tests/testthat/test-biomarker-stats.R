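test_that("Mann-Whitney micro-examples match the enumeration oracle", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$p, oracle_mw_exact_p(c(1, 2), c(3, 4)))

  r2 <- mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 2 / 70)
  expect_equal(r2$p, oracle_mw_exact_p(c(1, 2, 3, 4), c(5, 6, 7, 8)))
})

test_that("identical samples give U = n1*n2/2 and p = 1", {
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 4.5)
  expect_equal(r$p, 1)
  d <- mann_whitney(c(2, 2), c(2, 2, 2))
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  expect_equal(d$U, 3)
  expect_error(mann_whitney(numeric(0), 1), class = "mirmibc_stat_error")
})

test_that("exact p equals full-enumeration oracle on random tie-free inputs", {
  withr::with_seed(11, {
    for (rep in 1:30) {
      n1 <- sample(2:5, 1)
      n2 <- sample(2:5, 1)
      v <- sample(seq_len(100), n1 + n2) # distinct integers: tie-free
      x <- v[seq_len(n1)]
      y <- v[-seq_len(n1)]
      r <- mann_whitney(x, y)
      expect_true(r$exact)
      expect_equal(r$p, oracle_mw_exact_p(x, y),
                   info = paste("n1 =", n1, "n2 =", n2))
    }
  })
})

test_that("Kruskal-Wallis matches the hand-computed H and handles edge cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  # rank sums 6 / 15 / 24: H = 12/(9*10) * (36+225+576)/3 - 3*10 = 7.2
  expect_equal(kw$H, 7.2)
  expect_equal(kw$p, pchisq(7.2, df = 2, lower.tail = FALSE))

  same <- kruskal_wallis(list(c(5, 5), c(5, 5), c(5)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_error(kruskal_wallis(list(1:3, 4:6)), class = "mirmibc_stat_error")
})

test_that("two-group H is consistent with the U statistic normal z^2", {
  withr::with_seed(21, {
    x <- rnorm(30)
    y <- rnorm(25, 0.8)
    kt <- stats::kruskal.test(list(x, y)) # internal cross-check route
    mw <- mann_whitney(x, y)
    n1 <- 30; n2 <- 25; n <- n1 + n2
    z <- (mw$U - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
    expect_equal(unname(kt$statistic), z^2, tolerance = 1e-10)
  })
})

test_that("AUC equals brute-force pairwise concordance", {
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  labels <- rep(c("MIBC", "pTa_lg"), each = 3)
  r <- roc_auc(scores, labels, positive = "MIBC")
  expect_equal(r$auc, 8 / 9)
  expect_equal(r$auc, oracle_auc(scores, labels, "MIBC"))

  sep <- roc_auc(c(5, 6, 1, 2), rep(c("MIBC", "pTa_lg"), each = 2))
  expect_equal(sep$auc, 1.0)
  expect_equal(roc_auc(rep(1, 6), labels)$auc, 0.5) # all tied
  expect_error(roc_auc(1:3, rep("MIBC", 3)), class = "mirmibc_stat_error")
})

test_that("AUC identities hold on random data and match pROC", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- 30
      labels <- sample(rep(c("MIBC", "pTa_lg"), c(12, 18)))
      scores <- rnorm(n) + (labels == "MIBC")
      r <- roc_auc(scores, labels, positive = "MIBC")
      expect_equal(r$auc, oracle_auc(scores, labels, "MIBC"))
      # complement identity for tie-free scores
      expect_equal(roc_auc(-scores, labels, positive = "MIBC")$auc, 1 - r$auc)
      # U-derived estimator on the same data
      mw <- mann_whitney(scores[labels == "MIBC"], scores[labels == "pTa_lg"])
      expect_equal(r$auc, mw$U / (12 * 18))
    }
    skip_if_not_installed("pROC")
    labels <- sample(rep(c("MIBC", "pTa_lg"), c(15, 15)))
    scores <- rnorm(30) + 0.7 * (labels == "MIBC")
    expect_equal(
      roc_auc(scores, labels, positive = "MIBC")$auc,
      as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("pTa_lg", "MIBC"),
                                     direction = "<", quiet = TRUE))))
  })
})

test_that("ROC operating points form a monotone staircase between the corners", {
  withr::with_seed(41, {
    scores <- rnorm(40)
    labels <- sample(rep(c("MIBC", "pTa_lg"), 20))
    pts <- roc_auc(scores, labels)$points
    expect_equal(pts$sensitivity[1], 0)
    expect_equal(pts$specificity[1], 1)
    expect_equal(pts$sensitivity[nrow(pts)], 1)
    expect_equal(pts$specificity[nrow(pts)], 0)
    expect_true(all(diff(pts$sensitivity) >= 0))
    expect_true(all(diff(pts$specificity) <= 0))
  })
})

test_that("feature correlation defaults to rank-based and is symmetric", {
  expect_equal(feature_correlation(1:10, (1:10)^3), 1.0)
  expect_equal(feature_correlation(1:10, -(1:10)^3), -1.0)
  expect_equal(feature_correlation(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_equal(feature_correlation(c(1, 2, 3), c(2, 1, 3)),
               feature_correlation(c(2, 1, 3), c(1, 2, 3)))
  expect_equal(feature_correlation(1:5, c(2, 4, 5, 3, 1), method = "pearson"),
               stats::cor(1:5, c(2, 4, 5, 3, 1)))
  expect_warning(v <- feature_correlation(rep(1, 5), 1:5), "variance")
  expect_true(is.na(v))
})

test_that("the biomarker table reports the source-stratified comparisons", {
  expr <- toy_expression(seed = 2)
  tbl <- biomarker_table(expr, mirnas = c("mirA", "mirB"))
  expect_setequal(unique(tbl$comparison),
                  paste0("pTa_lg-MIBC (", c("TURB", "CYS", "all"), ")"))
  strong <- tbl[tbl$mirna == "mirA" & grepl("all", tbl$comparison), ]
  expect_true(all(strong$significant))
  expect_true(all(strong$auc > 0.9))
  weak <- tbl[tbl$mirna == "mirB" & grepl("all", tbl$comparison), ]
  expect_true(all(weak$p > 0.001)) # null miRNA should rarely look strong
})
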