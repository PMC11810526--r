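test_that("knn_fit validates k, classes and feature variance", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("MIBC", "pTa_lg"), 5)
  expect_s3_class(knn_fit(x, y, 1), "fitted_knn")
  expect_error(knn_fit(x, y, 11), class = "mirmibc_model_error")
  expect_error(knn_fit(x, y, 4), class = "mirmibc_model_error") # even k
  expect_error(knn_fit(x, rep("MIBC", 10), 3), class = "mirmibc_model_error")
  xc <- x; xc[, 2] <- 7
  expect_error(knn_fit(xc, y, 3), class = "mirmibc_model_error", regexp = "f2")
})

test_that("knn probabilities are neighbour-vote fractions", {
  # query equal to a training point, k = 1
  x <- matrix(c(0, 5), 2, 1, dimnames = list(NULL, "f"))
  m1 <- knn_fit(x, c("MIBC", "pTa_lg"), 1)
  expect_equal(knn_predict_proba(m1, matrix(c(f = 0), 1, 1,
                                            dimnames = list(NULL, "f")))[1, ],
               c(MIBC = 1, pTa_lg = 0))

  # 1-D: class A (=MIBC) at {0, 1}, class B at {10}; k = 3, query 0.5
  x2 <- matrix(c(0, 1, 10), 3, 1, dimnames = list(NULL, "f"))
  m3 <- knn_fit(x2, c("MIBC", "MIBC", "pTa_lg"), 3)
  p <- knn_predict_proba(m3, matrix(c(f = 0.5), 1, 1,
                                    dimnames = list(NULL, "f")))
  expect_equal(unname(p[1, "MIBC"]), 2 / 3)
  expect_equal(sum(p), 1)
})

test_that("k = 19 probabilities are exact multiples of 1/19", {
  withr::with_seed(7, {
    x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c("MIBC", "pTa_lg"), 15)
    m <- knn_fit(x, y, 19)
    p <- knn_predict_proba(m, matrix(rnorm(20), 10, 2,
                                     dimnames = list(NULL, c("a", "b"))))
    expect_true(all(abs(p * 19 - round(p * 19)) < 1e-12))
    expect_equal(rowSums(p), rep(1, 10))
  })
})

test_that("native KNN equals the brute-force oracle on 200 random instances", {
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(10:50, 1)
      d <- sample(1:4, 1)
      k <- sample(seq(1, min(n, 15), by = 2), 1)
      x <- matrix(rnorm(n * d), n, d,
                  dimnames = list(NULL, paste0("f", seq_len(d))))
      y <- c("MIBC", "pTa_lg", sample(c("MIBC", "pTa_lg"), n - 2, replace = TRUE))
      m <- knn_fit(x, y, k)
      q <- matrix(rnorm(d), 1, d, dimnames = list(NULL, paste0("f", seq_len(d))))
      expect_equal(knn_predict_proba(m, q)[1, ],
                   oracle_knn_proba(x, y, k, as.numeric(q),
                                    m$center, m$scale))
    }
  })
})

test_that("KNN is invariant to training-sample order away from distance ties", {
  withr::with_seed(13, {
    x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c("MIBC", "pTa_lg"), 20)
    q <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
    m <- knn_fit(x, y, 7)
    perm <- sample(40)
    mp <- knn_fit(x[perm, ], y[perm], 7)
    expect_equal(knn_predict_proba(m, q), knn_predict_proba(mp, q))
  })
})

test_that("every family honours the probabilistic-classifier contract", {
  withr::with_seed(2, {
    n <- 60
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rep(c("MIBC", "pTa_lg"), each = n / 2)
    x[y == "MIBC", 1] <- x[y == "MIBC", 1] + 2
    newx <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  })
  for (fam in c("knn", "svm_poly", "vnn", "random_forest", "boosting")) {
    fit <- fit_classifier(make_classifier(fam), x, y, seed = 5)
    p <- predict_proba(fit, newx)
    expect_true(all(p >= 0 & p <= 1), info = fam)
    expect_equal(unname(rowSums(p)), rep(1, 10), info = fam)
    refit <- fit_classifier(make_classifier(fam), x, y, seed = 5)
    expect_equal(p, predict_proba(refit, newx), info = fam)
    # argmax prediction consistent with the probabilities
    expect_equal(as.character(predict_class(p)),
                 mibc_classes()[1 + (p[, "pTa_lg"] > p[, "MIBC"])], info = fam)
  }
})

test_that("make_classifier enforces family and hyperparameter schema", {
  expect_equal(make_classifier("knn", list(k = 19))$hyperparams$k, 19)
  # printed defaults of the study's best VNN and SVM are the constructor defaults
  expect_equal(make_classifier("vnn")$hyperparams, list(size = 4, decay = 0.01))
  expect_equal(make_classifier("svm_poly")$hyperparams,
               list(C = 1, degree = 2, scale = 0.1))
  expect_error(make_classifier("lda"), class = "mirmibc_model_error")
  expect_error(make_classifier("knn", list(bogus = 1)),
               class = "mirmibc_model_error")
  expect_error(make_classifier("knn", list(k = -3)),
               class = "mirmibc_model_error")
})

test_that("prediction refuses mismatched or incomplete features", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("MIBC", "pTa_lg"), 10)
  fit <- fit_classifier(make_classifier("knn", list(k = 3)), x, y)
  bad <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "z")))
  expect_error(predict_proba(fit, bad), class = "mirmibc_model_error")
  withna <- x[1:3, ]; withna[1, 1] <- NA
  expect_error(predict_proba(fit, withna), class = "mirmibc_model_error")
})
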