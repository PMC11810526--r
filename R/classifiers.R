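#' Fit the native k-nearest-neighbour classifier
#'
#' Stores the training matrix standardized per feature (center = training
#' mean, scale = training sd) together with the labels and the transform.
#' `k` must be odd so that the two-class neighbour vote can never tie.
#'
#' @param x Numeric feature matrix or data frame (no missing values).
#' @param y Class labels coercible to the canonical two-class factor.
#' @param k Odd positive neighbour count, `k <= nrow(x)`.
#' @return A `fitted_knn` object.
#' @export
knn_fit <- function(x, y, k) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_class_factor(y)
  if (anyNA(x)) rlang::abort("Missing feature values.", class = "mirmibc_model_error")
  if (nlevels(droplevels(y)) < 2) {
    rlang::abort("Both classes must be present in the training labels.",
                 class = "mirmibc_model_error")
  }
  k <- as.integer(k)
  if (k < 1 || k %% 2 == 0) {
    rlang::abort("k must be a positive odd integer.", class = "mirmibc_model_error")
  }
  if (k > nrow(x)) {
    rlang::abort(sprintf("k = %d exceeds the %d training samples.", k, nrow(x)),
                 class = "mirmibc_model_error")
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  const <- which(scl == 0)
  if (length(const) > 0) {
    rlang::abort(paste0("Constant feature(s): ",
                        paste(colnames(x)[const], collapse = ", ")),
                 class = "mirmibc_model_error")
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(
    list(k = k, x = xs, y = y, center = ctr, scale = scl,
         features = colnames(x)),
    class = "fitted_knn")
}

#' KNN class probabilities by neighbour vote
#'
#' For each query, the k nearest training points under Euclidean distance on
#' the standardized features vote; P(class) is the vote fraction, an exact
#' multiple of 1/k, so the two probabilities sum to 1 by construction.
#' Distance ties at the k-th neighbour are broken by including the point
#' with the lower training index (stable ordering).
#'
#' @param model A `fitted_knn`.
#' @param newx Query feature matrix/data frame with the model's features.
#' @return Numeric matrix, one row per query, columns `MIBC` and `pTa_lg`.
#' @export
knn_predict_proba <- function(model, newx) {
  newx <- as.matrix(newx)
  storage.mode(newx) <- "double"
  if (!is.null(model$features)) {
    if (is.null(colnames(newx)) || !all(model$features %in% colnames(newx))) {
      rlang::abort("Query features do not match the model's feature subset.",
                   class = "mirmibc_model_error")
    }
    newx <- newx[, model$features, drop = FALSE]
  }
  if (anyNA(newx)) rlang::abort("Missing feature values in query.",
                                class = "mirmibc_model_error")
  qs <- sweep(sweep(newx, 2, model$center), 2, model$scale, "/")
  # squared Euclidean distances, queries x training points
  d2 <- outer(rowSums(qs^2), rep(1, nrow(model$x))) +
    outer(rep(1, nrow(qs)), rowSums(model$x^2)) - 2 * qs %*% t(model$x)
  cls <- mibc_classes()
  p <- t(apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(model$k)] # order() is stable: ties -> lower index
    votes <- tabulate(model$y[nn], nbins = 2)
    votes / model$k
  }))
  colnames(p) <- cls
  rownames(p) <- rownames(newx)
  p
}

#' Declare a probability-emitting classifier
#'
#' Uniform constructor for the five algorithm families used in the model
#' search. KNN is the native implementation; the other four families are
#' fulfilled by established implementations behind the same contract: for
#' every sample the two class probabilities lie in \[0, 1\] and sum to 1,
#' and the predicted class is the argmax.
#'
#' Default hyperparameters are the tuned values reported for the study's
#' best models where available: KNN k = 19; VNN single hidden layer,
#' size = 4, decay = 0.01; polynomial SVM C = 1, degree = 2, scale = 0.1.
#'
#' @param family One of `"knn"`, `"svm_poly"`, `"vnn"`, `"random_forest"`,
#'   `"boosting"`.
#' @param hyperparams Named list overriding the family defaults; unknown
#'   names are an error.
#' @return A `classifier_spec` object; fit it with [fit_classifier()].
#' @export
make_classifier <- function(family, hyperparams = list()) {
  defaults <- list(
    knn = list(k = 19),
    svm_poly = list(C = 1, degree = 2, scale = 0.1),
    vnn = list(size = 4, decay = 0.01),
    random_forest = list(ntree = 500),
    boosting = list(nrounds = 100)
  )
  if (!family %in% names(defaults)) {
    rlang::abort(paste0("Unknown classifier family '", family, "'. Use one of: ",
                        paste(names(defaults), collapse = ", ")),
                 class = "mirmibc_model_error")
  }
  hp <- defaults[[family]]
  extra <- setdiff(names(hyperparams), names(hp))
  if (length(extra) > 0) {
    rlang::abort(paste0("Unknown hyperparameter(s) for ", family, ": ",
                        paste(extra, collapse = ", ")),
                 class = "mirmibc_model_error")
  }
  hp[names(hyperparams)] <- hyperparams
  bad <- vapply(hp, function(v) !is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0,
                logical(1))
  if (any(bad)) {
    rlang::abort(paste0("Malformed hyperparameter(s): ",
                        paste(names(hp)[bad], collapse = ", ")),
                 class = "mirmibc_model_error")
  }
  structure(list(family = family, hyperparams = hp), class = "classifier_spec")
}

#' Fit a declared classifier
#'
#' Standardizes the features on the training data only (center/scale learned
#' here and reapplied at prediction time) and fits the family's backing
#' implementation. Randomized fits (SVM probability calibration, neural-net
#' initialization, forests, boosting subsampling) are run under `seed`, so a
#' fixed seed gives a deterministic model.
#'
#' @param spec A `classifier_spec` from [make_classifier()].
#' @param x Training feature matrix/data frame.
#' @param y Training labels.
#' @param seed Integer seed for any randomness in the fit.
#' @return A `fitted_classifier` carrying the spec, transform and fit.
#' @export
fit_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_class_factor(y)
  if (anyNA(x)) rlang::abort("Missing feature values.", class = "mirmibc_model_error")
  hp <- spec$hyperparams
  if (spec$family == "knn") {
    fit <- knn_fit(x, y, k = hp$k)
    return(structure(list(spec = spec, fit = fit, features = colnames(x),
                          classes = mibc_classes()),
                     class = "fitted_classifier"))
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    rlang::abort("Constant feature in training data.", class = "mirmibc_model_error")
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  fit <- withr::with_seed(seed, switch(
    spec$family,
    svm_poly = kernlab::ksvm(
      xs, y, kernel = "polydot",
      kpar = list(degree = hp$degree, scale = hp$scale, offset = 1),
      C = hp$C, prob.model = TRUE, scaled = FALSE),
    vnn = {
      df <- data.frame(xs)
      df$.class <- y
      nnet::nnet(.class ~ ., data = df, size = hp$size, decay = hp$decay,
                 maxit = 500, trace = FALSE)
    },
    random_forest = randomForest::randomForest(xs, y, ntree = hp$ntree),
    boosting = xgboost::xgboost(
      xs, y, nrounds = hp$nrounds, objective = "binary:logistic",
      max_depth = 3, learning_rate = 0.3, nthread = 1, verbosity = 0)
  ))
  structure(list(spec = spec, fit = fit, center = ctr, scale = scl,
                 features = colnames(x), classes = mibc_classes()),
            class = "fitted_classifier")
}

#' Class probabilities from a fitted classifier
#'
#' @param object A fitted model (`fitted_classifier` or `fitted_knn`).
#' @param newx Query features (must carry the model's feature subset, no
#'   missing values).
#' @param ... Unused.
#' @return Matrix of probabilities, columns `MIBC` and `pTa_lg`, rows
#'   summing to 1.
#' @export
predict_proba <- function(object, newx, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.fitted_knn <- function(object, newx, ...) {
  knn_predict_proba(object, newx)
}

#' @rdname predict_proba
#' @export
predict_proba.fitted_classifier <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  storage.mode(newx) <- "double"
  if (is.null(colnames(newx)) || !all(object$features %in% colnames(newx))) {
    rlang::abort("Query features do not match the model's feature subset.",
                 class = "mirmibc_model_error")
  }
  newx <- newx[, object$features, drop = FALSE]
  if (anyNA(newx)) rlang::abort("Missing feature values in query.",
                                class = "mirmibc_model_error")
  if (object$spec$family == "knn") {
    return(knn_predict_proba(object$fit, newx))
  }
  xs <- sweep(sweep(newx, 2, object$center), 2, object$scale, "/")
  p_mibc <- switch(
    object$spec$family,
    svm_poly = {
      pr <- kernlab::predict(object$fit, xs, type = "probabilities")
      pr[, "MIBC"] / rowSums(pr)
    },
    vnn = {
      raw <- as.numeric(stats::predict(object$fit, data.frame(xs), type = "raw"))
      1 - raw # nnet's raw output is P(second level) = P(pTa_lg)
    },
    random_forest = {
      pr <- stats::predict(object$fit, xs, type = "prob")
      pr[, "MIBC"]
    },
    boosting = {
      # with a factor response xgboost's response is P(second level) = P(pTa_lg)
      1 - as.numeric(stats::predict(object$fit, xs, type = "response"))
    }
  )
  p_mibc <- pmin(1, pmax(0, as.numeric(p_mibc)))
  p <- cbind(MIBC = p_mibc, pTa_lg = 1 - p_mibc)
  rownames(p) <- rownames(newx)
  p
}

#' Argmax class from a probability matrix
#'
#' Exact probability ties resolve to the canonical class order (MIBC first).
#'
#' @param p Probability matrix with columns `MIBC`, `pTa_lg`.
#' @return Factor of predicted classes.
#' @export
predict_class <- function(p) {
  p <- p[, mibc_classes(), drop = FALSE]
  factor(mibc_classes()[max.col(p, ties.method = "first")],
         levels = mibc_classes())
}
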