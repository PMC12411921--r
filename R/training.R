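#' Training configuration for the dense softmax head
#'
#' Mirrors the study settings: Adam optimizer, sparse categorical
#' cross-entropy, 20 epochs, batch size 64, with optional balanced class
#' weighting for the 96/30/36 imbalance. All stochasticity (shuffling,
#' dropout masks) is derived from `seed`.
#'
#' @param optimizer Only `"adam"` is implemented.
#' @param epochs Number of passes over the training set (default 20).
#' @param batch_size Minibatch size (default 64).
#' @param split Train fraction for convenience bookkeeping (default 0.7).
#' @param class_weighting Apply balanced inverse-frequency sample weights
#'   (default `TRUE`).
#' @param learning_rate Adam step size (default 0.05; the head is a linear
#'   softmax layer over standardized features, which tolerates an aggressive
#'   step).
#' @param dropout Dropout rate applied to the blended feature vector during
#'   training (default 0.25, matching the branch configuration).
#' @param seed Integer seed.
#' @return Object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", epochs = 20, batch_size = 64,
                         split = 0.7, class_weighting = TRUE,
                         learning_rate = 0.05, dropout = 0.25, seed = 1) {
  assert_that(identical(optimizer, "adam"), "only the adam optimizer is implemented")
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  assert_that(split > 0 && split < 1, "split must be in (0, 1)")
  assert_that(learning_rate > 0, "learning_rate must be > 0")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(optimizer = optimizer, loss = "sparse_categorical_crossentropy",
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 split = split, class_weighting = isTRUE(class_weighting),
                 learning_rate = learning_rate, dropout = dropout,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Balanced inverse-frequency class weights
#'
#' `w_c = n_total / (n_classes * n_c)`: classes rarer than average get
#' weight > 1. For the study's counts (ARR 96, CHF 30, NSR 36) this gives
#' (0.5625, 1.8, 1.5).
#'
#' @param counts Named positive counts per class.
#' @return Named numeric weights in the same order.
#' @examples
#' class_weights(c(ARR = 96, CHF = 30, NSR = 36))
#' @export
class_weights <- function(counts) {
  assert_that(length(counts) >= 2, "need at least two classes")
  assert_that(all(counts > 0), "all class counts must be > 0")
  w <- sum(counts) / (length(counts) * counts)
  stats::setNames(as.numeric(w), names(counts))
}

#' Stratified train/test split
#'
#' Splits record ids class by class so that class proportions are preserved.
#' The test side of each class gets `round((1 - train_fraction) * n_c)`
#' members (clamped so both sides keep at least one record); for the study
#' counts (96, 30, 36) at 70:30 this yields test sizes (29, 9, 11). The
#' split is a deterministic function of `seed` and is disjoint and
#' exhaustive by construction.
#'
#' @param manifest Data frame with `record_id` and `label` columns (e.g. an
#'   `ecg_manifest`), or anything [class_counts()] accepts.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
stratified_split <- function(manifest, train_fraction, seed) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  labels <- as_class_factor(manifest$label)
  ids <- as.character(manifest$record_id)
  train <- character(0); test <- character(0)
  withr::with_seed(as.integer(seed), {
    for (cls in ECG_CLASSES) {
      cls_ids <- sort(ids[labels == cls])
      n <- length(cls_ids)
      if (n == 0) next
      assert_that(n >= 2, "class ", cls, " has fewer than 2 members")
      n_test <- round((1 - train_fraction) * n)
      n_test <- min(max(n_test, 1L), n - 1L)
      perm <- sample(cls_ids)
      test <- c(test, perm[seq_len(n_test)])
      train <- c(train, perm[(n_test + 1):n])
    }
  })
  list(train = sort(train), test = sort(test))
}

#' Stratified k-fold partition
#'
#' Shuffles each class once (seeded) and deals members to folds in
#' round-robin order, so fold sizes per class differ by at most one. With
#' counts (96, 30, 36) and k = 5 every fold holds exactly 6 CHF records.
#'
#' @inheritParams stratified_split
#' @param k Number of folds (default 5); every class must have >= k members.
#' @return List of `k` elements, each `list(train =, test =)` of record ids;
#'   the test sets partition the manifest.
#' @export
stratified_kfold <- function(manifest, k = 5, seed = 1) {
  labels <- as_class_factor(manifest$label)
  ids <- as.character(manifest$record_id)
  fold_of <- stats::setNames(integer(length(ids)), ids)
  withr::with_seed(as.integer(seed), {
    for (cls in ECG_CLASSES) {
      cls_ids <- sort(ids[labels == cls])
      n <- length(cls_ids)
      if (n == 0) next
      assert_that(n >= k, "class ", cls, " has ", n, " members, fewer than k = ", k)
      perm <- sample(cls_ids)
      fold_of[perm] <- rep(seq_len(k), length.out = n)
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = sort(ids[fold_of[ids] != f]),
         test = sort(ids[fold_of[ids] == f]))
  })
}

# ---- dense softmax head training (Adam) -------------------------------------

# Trains (hidden ReLU layers +) a softmax output layer on a feature matrix
# with per-sample weights, by minibatch Adam on the weighted cross-entropy.
# Features are standardized with train-set statistics inside the head.
train_head_adam <- function(X, y, cfg, sample_weights, dense_units = integer(0),
                            seed = cfg$seed) {
  n <- nrow(X); p <- ncol(X); K <- length(ECG_CLASSES)
  assert_that(n > 0, "empty training set")
  mu <- colMeans(X)
  sd_ <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  sd_[sd_ < 1e-8] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sd_, "/")
  yi <- as.integer(y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi)] <- 1
  w <- sample_weights
  withr::with_seed(as.integer(seed), {
    hidden <- list()
    in_dim <- p
    for (h in dense_units) {
      hidden[[length(hidden) + 1]] <- list(W = he_uniform(in_dim, h),
                                           b = rep(0, h))
      in_dim <- h
    }
    W <- matrix(0, in_dim, K); b <- rep(0, K)
    adam <- function() list(m = 0, v = 0)
    st <- list(W = adam(), b = adam(),
               hW = lapply(hidden, function(.) adam()),
               hb = lapply(hidden, function(.) adam()))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
    step <- function(param, grad, state) {
      state$m <- beta1 * state$m + (1 - beta1) * grad
      state$v <- beta2 * state$v + (1 - beta2) * grad^2
      mhat <- state$m / (1 - beta1^t)
      vhat <- state$v / (1 - beta2^t)
      list(param = param - cfg$learning_rate * mhat / (sqrt(vhat) + eps),
           state = state)
    }
    history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c(); sizes <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        Zb <- Z[idx, , drop = FALSE]
        if (cfg$dropout > 0) {
          mask <- matrix(stats::rbinom(length(Zb), 1, 1 - cfg$dropout),
                         nrow(Zb), ncol(Zb)) / (1 - cfg$dropout)
          Zb <- Zb * mask
        }
        acts <- list(Zb)
        A <- Zb
        for (l in seq_along(hidden)) {
          A <- sweep(A %*% hidden[[l]]$W, 2, hidden[[l]]$b, "+")
          A[A < 0] <- 0
          acts[[l + 1]] <- A
        }
        P <- softmax_rows(sweep(A %*% W, 2, b, "+"))
        wb <- w[idx]
        ce <- -log(pmax(P[cbind(seq_along(idx), yi[idx])], 1e-12))
        losses <- c(losses, sum(wb * ce)); sizes <- c(sizes, sum(wb))
        G <- (P - Y[idx, , drop = FALSE]) * wb / length(idx)
        t <- t + 1
        gW <- crossprod(A, G); gb <- colSums(G)
        upd <- step(W, gW, st$W); W <- upd$param; st$W <- upd$state
        upd <- step(b, gb, st$b); b <- upd$param; st$b <- upd$state
        if (length(hidden) > 0) {
          delta <- G %*% t(W)
          for (l in rev(seq_along(hidden))) {
            delta <- delta * (acts[[l + 1]] > 0)
            gHW <- crossprod(acts[[l]], delta)
            gHb <- colSums(delta)
            upd <- step(hidden[[l]]$W, gHW, st$hW[[l]])
            hidden[[l]]$W <- upd$param; st$hW[[l]] <- upd$state
            upd <- step(hidden[[l]]$b, gHb, st$hb[[l]])
            hidden[[l]]$b <- upd$param; st$hb[[l]] <- upd$state
            delta <- delta %*% t(hidden[[l]]$W)
          }
        }
      }
      history[ep] <- sum(losses) / sum(sizes)
    }
    list(head = list(mu = mu, sd = sd_, hidden = hidden, W = W, b = b),
         history = history)
  })
}

#' Train the dense softmax head of a model
#'
#' Blends the training images' branch features at the model's alpha and fits
#' the softmax head by minibatch Adam on the (optionally class-weighted)
#' cross-entropy. Branch filters stay fixed; see the methods vignette for
#' why the trainable part of this implementation is the head.
#'
#' @param model An [build_model()] object.
#' @param images Training images ([compute_images()] output) or a
#'   [compute_branch_features()] result.
#' @param cfg A [train_config()].
#' @return The model with `head` filled in and `history` (one weighted loss
#'   per epoch) attached.
#' @export
train_model <- function(model, images, cfg = train_config()) {
  assert_that(inherits(cfg, "train_config"), "cfg must be a train_config")
  feats <- if (is.list(images) && !is.null(images$fs)) images
           else compute_branch_features(model, images)
  assert_that(nrow(feats$fs) > 0, "empty training set")
  X <- unclass(blend(feats$fs, feats$fb, model$blend))
  y <- feats$labels
  w <- rep(1, length(y))
  if (cfg$class_weighting) {
    counts <- table(y)
    assert_that(all(counts > 0), "every class must be present in the training set")
    cw <- class_weights(stats::setNames(as.numeric(counts), names(counts)))
    w <- as.numeric(cw[as.character(y)])
  }
  fit <- train_head_adam(X, y, cfg, w, dense_units = model$dense_units)
  model$head <- fit$head
  model$history <- fit$history
  model$train_config <- cfg
  model
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a classifier on a test set
#'
#' Computes the 3x3 confusion matrix (rows = true class, columns =
#' predicted), accuracy as `trace / total` — the multiclass aggregate of the
#' one-vs-rest (TP+TN)/(TP+TN+FP+FN) form — per-class precision and recall,
#' and wall-clock time for the prediction pass.
#'
#' @param object A trained [build_model()] model or a fitted [fit_head()]
#'   head.
#' @param data Test images ([compute_images()] output), a
#'   [compute_branch_features()] result (for models), or a feature table /
#'   matrix (for heads).
#' @param labels True labels; taken from `data` when it carries them.
#' @return Object of class `eval_result` with fields `confusion`,
#'   `accuracy`, `per_class` (tibble), `wall_time_s`, `n`.
#' @export
evaluate <- function(object, data, labels = NULL) UseMethod("evaluate")

#' @export
evaluate.ecgblend_model <- function(object, data, labels = NULL) {
  feats <- if (is.list(data) && !is.null(data$fs)) data
           else compute_branch_features(object, data)
  labels <- labels %||% feats$labels
  t0 <- proc.time()[["elapsed"]]
  pred <- predict(object, feats)$.pred
  wall <- proc.time()[["elapsed"]] - t0
  eval_result(labels, pred, wall)
}

#' @export
evaluate.ml_head <- function(object, data, labels = NULL) {
  if (is.data.frame(data) && "label" %in% names(data) && is.null(labels)) {
    labels <- data$label
  }
  t0 <- proc.time()[["elapsed"]]
  pred <- predict_head(object, data)$.pred
  wall <- proc.time()[["elapsed"]] - t0
  eval_result(labels, pred, wall)
}

eval_result <- function(truth, pred, wall_time_s = NA_real_) {
  assert_that(length(truth) > 0, "empty test set")
  truth <- as_class_factor(truth)
  pred <- factor(as.character(pred), levels = ECG_CLASSES)
  cm <- table(truth = truth, pred = pred)
  cm <- matrix(as.integer(cm), 3, 3, dimnames = list(ECG_CLASSES, ECG_CLASSES))
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  structure(list(confusion = cm, accuracy = acc,
                 per_class = tibble::tibble(class = ECG_CLASSES,
                                            precision = as.numeric(prec),
                                            recall = as.numeric(rec)),
                 wall_time_s = wall_time_s, n = length(truth)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy %.4f on n = %d\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-class metrics of an evaluation
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return Tibble with one row per class: precision, recall, support.
#' @export
tidy.eval_result <- function(x, ...) {
  dplyr::mutate(x$per_class, support = rowSums(x$confusion))
}

#' One-row summary of an evaluation
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return Tibble with `accuracy`, `n`, `wall_time_s`.
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n, wall_time_s = x$wall_time_s)
}
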