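#' Specification of a classical ML classification head
#'
#' The faster alternatives to the dense softmax head: support vector machine
#' (RBF kernel, C = 1), random forest (200 trees), k-nearest neighbours
#' (k = 5, Euclidean) and XGBoost (200 rounds, depth 4, eta 0.1). Features
#' are standardized with train-set statistics before SVM and KNN; the tree
#' methods consume raw features.
#'
#' @param algorithm One of `"svm"`, `"rf"`, `"knn"`, `"xgboost"`.
#' @param hyperparams Named list overriding the defaults above.
#' @param seed Integer seed (RF and XGBoost are seed-deterministic).
#' @return Object of class `ml_head_spec`.
#' @export
ml_head_spec <- function(algorithm = c("svm", "rf", "knn", "xgboost"),
                         hyperparams = list(), seed = 1) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm = list(cost = 1, kernel = "radial"),
    rf = list(ntree = 200),
    knn = list(k = 5),
    xgboost = list(nrounds = 200, max_depth = 4, eta = 0.1))
  hp <- utils::modifyList(defaults, hyperparams)
  structure(list(algorithm = algorithm, hyperparams = hp, seed = as.integer(seed)),
            class = "ml_head_spec")
}

split_feature_table <- function(features, labels) {
  if (is.data.frame(features)) {
    if ("label" %in% names(features)) {
      labels <- labels %||% features$label
      features <- features[setdiff(names(features), "label")]
    }
    features <- as.matrix(features)
  }
  assert_that(!is.null(labels), "labels are required")
  assert_that(nrow(features) > 0 && ncol(features) > 0, "empty feature table")
  assert_that(!anyNA(features), "feature table contains missing values")
  list(X = features, y = as_class_factor(labels))
}

#' Fit a classical ML head on a blended feature table
#'
#' @param features Feature table from [extract_blended_features()] (a tibble
#'   with a `label` column), or a bare numeric matrix.
#' @param labels Class labels, if not carried by `features`.
#' @param spec An [ml_head_spec()].
#' @return Object of class `ml_head` storing the fitted model, the
#'   standardization statistics (SVM/KNN), and training metadata
#'   (`n`, `n_features`, `class_counts`).
#' @export
fit_head <- function(features, labels = NULL, spec = ml_head_spec("rf")) {
  assert_that(inherits(spec, "ml_head_spec"), "spec must be an ml_head_spec")
  d <- split_feature_table(features, labels)
  X <- d$X; y <- d$y
  present <- table(droplevels(y))
  assert_that(length(present) >= 2,
              "training set contains a single class (", names(present)[1], ")")
  standardize <- spec$algorithm %in% c("svm", "knn")
  mu <- NULL; sd_ <- NULL
  if (standardize) {
    mu <- colMeans(X)
    sd_ <- apply(X, 2, stats::sd)
    sd_[!is.finite(sd_) | sd_ < 1e-8] <- 1
    X <- sweep(sweep(X, 2, mu, "-"), 2, sd_, "/")
  }
  hp <- spec$hyperparams
  fit <- withr::with_seed(spec$seed, switch(spec$algorithm,
    svm = e1071::svm(x = X, y = y, kernel = hp$kernel, cost = hp$cost,
                     probability = TRUE, scale = FALSE),
    rf = randomForest::randomForest(x = X, y = y, ntree = hp$ntree),
    knn = list(X = X, y = y, k = hp$k),
    xgboost = xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = 3,
                    max_depth = hp$max_depth, eta = hp$eta, nthread = 1,
                    seed = spec$seed),
      data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L, nthread = 1),
      nrounds = hp$nrounds)))
  structure(list(spec = spec, fit = fit, mu = mu, sd = sd_,
                 n = nrow(X), n_features = ncol(X),
                 class_counts = stats::setNames(
                   as.integer(table(y)), levels(y))),
            class = "ml_head")
}

#' Predict with a fitted ML head
#'
#' Predictions are row-wise independent: permuting input rows permutes the
#' output identically.
#'
#' @param head An [fit_head()] result.
#' @param features Feature table or matrix with the same dimensionality the
#'   head was fitted on (a `label` column, if present, is ignored).
#' @return Tibble with `.pred` (factor) and nonnegative per-class score
#'   columns `ARR`, `CHF`, `NSR` (probabilities for SVM/RF/XGBoost; one-hot
#'   winning-vote indicators for KNN).
#' @export
predict_head <- function(head, features) {
  assert_that(inherits(head, "ml_head"), "head must come from fit_head()")
  if (is.data.frame(features)) {
    features <- as.matrix(features[setdiff(names(features), "label")])
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  assert_that(ncol(features) == head$n_features,
              "feature dimension mismatch: got ", ncol(features),
              ", head was fitted on ", head$n_features)
  X <- features
  if (!is.null(head$mu)) {
    X <- sweep(sweep(X, 2, head$mu, "-"), 2, head$sd, "/")
  }
  spec <- head$spec
  out <- switch(spec$algorithm,
    svm = {
      pr <- predict(head$fit, X, probability = TRUE)
      probs <- attr(pr, "probabilities")[, ECG_CLASSES, drop = FALSE]
      list(pred = as.character(pr), scores = probs)
    },
    rf = {
      probs <- predict(head$fit, X, type = "prob")[, ECG_CLASSES, drop = FALSE]
      list(pred = as.character(predict(head$fit, X)), scores = probs)
    },
    knn = {
      pred <- withr::with_seed(spec$seed,
        as.character(class::knn(head$fit$X, X, head$fit$y, k = head$fit$k)))
      scores <- matrix(0, length(pred), 3, dimnames = list(NULL, ECG_CLASSES))
      scores[cbind(seq_along(pred), match(pred, ECG_CLASSES))] <- 1
      list(pred = pred, scores = scores)
    },
    xgboost = {
      p <- predict(head$fit, xgboost::xgb.DMatrix(X, nthread = 1))
      probs <- if (is.matrix(p)) p else matrix(p, ncol = 3, byrow = TRUE)
      dimnames(probs) <- list(NULL, ECG_CLASSES)
      list(pred = ECG_CLASSES[max.col(probs, ties.method = "first")],
           scores = probs)
    })
  tibble::tibble(.pred = factor(out$pred, levels = ECG_CLASSES),
                 ARR = out$scores[, "ARR"], CHF = out$scores[, "CHF"],
                 NSR = out$scores[, "NSR"])
}
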