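#' Define an experiment grid
#'
#' One configuration object drives every harness run: the alpha values to
#' sweep, the train/test split ratios, the classification heads, the data
#' source and the master seed. All sub-seeds (dataset generation, branch
#' initialization, splits, head training) derive from `seed`, so every
#' report row is regenerable from the grid alone.
#'
#' @param alphas Blending proportions (default `seq(0.1, 0.9, by = 0.1)`).
#' @param splits Train fractions (default `c(0.6, 0.7, 0.8, 0.9)`).
#' @param heads Character vector of head names for [run_ml_sweep()]
#'   (default all four of svm/rf/knn/xgboost).
#' @param dataset `"synthetic"` (default) or `"directory"`.
#' @param dir Data directory when `dataset = "directory"` (a
#'   [load_manifest()] layout).
#' @param n_per_class Synthetic class counts (default the 96/30/36 study
#'   imbalance).
#' @param seed Master seed.
#' @param epochs,batch_size Dense-head training settings (defaults 20, 64).
#' @param segment_length,image_size Imaging settings (defaults 1000
#'   samples, 227 px).
#' @return Object of class `experiment_grid`.
#' @export
experiment_grid <- function(alphas = seq(0.1, 0.9, by = 0.1),
                            splits = c(0.6, 0.7, 0.8, 0.9),
                            heads = c("svm", "rf", "knn", "xgboost"),
                            dataset = c("synthetic", "directory"),
                            dir = NULL,
                            n_per_class = c(ARR = 96, CHF = 30, NSR = 36),
                            seed = 1, epochs = 20, batch_size = 64,
                            segment_length = 1000, image_size = 227L) {
  dataset <- match.arg(dataset)
  assert_that(length(alphas) > 0 && all(alphas >= 0 & alphas <= 1),
              "alphas must lie in [0, 1]")
  assert_that(length(splits) > 0 && all(splits > 0 & splits < 1),
              "splits must lie in (0, 1)")
  if (dataset == "directory") {
    assert_that(!is.null(dir), "dataset = 'directory' requires dir")
  }
  structure(list(alphas = alphas, splits = splits, heads = heads,
                 dataset = dataset, dir = dir, n_per_class = n_per_class,
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 segment_length = as.integer(segment_length),
                 image_size = as.integer(image_size)),
            class = "experiment_grid")
}

#' Prepare the cached, alpha-independent part of an experiment
#'
#' Resolves the dataset (generating it when synthetic), images every record
#' once, builds the model and computes both branch feature matrices. Sweeps
#' over alpha, splits and heads all reuse this cache, since none of them
#' affect imaging or the fixed branch filters.
#'
#' @param grid An [experiment_grid()].
#' @param records Optional pre-built record list (overrides the grid's data
#'   source; used for probe datasets).
#' @return List with `grid`, `records`, `images`, `model`, `features`
#'   ([compute_branch_features()] result), `manifest` (tibble of
#'   `record_id`, `label`) and `timing` (imaging/feature seconds).
#' @export
prepare_experiment <- function(grid, records = NULL) {
  assert_that(inherits(grid, "experiment_grid"), "grid must be an experiment_grid")
  if (is.null(records)) {
    records <- if (grid$dataset == "synthetic") {
      generate_dataset(synth_spec(n_per_class = grid$n_per_class,
                                  seed = derive_seed(grid$seed, 10)))
    } else {
      m <- tryCatch(load_manifest(grid$dir),
                    error = function(e) stop_ecg(
                      conditionMessage(e),
                      " — no dataset at '", grid$dir,
                      "'; generate one with generate_dataset() + write_dataset()"))
      load_records(m)
    }
  }
  t0 <- proc.time()[["elapsed"]]
  images <- compute_images(records, segment_length = grid$segment_length,
                           image_size = grid$image_size)
  t1 <- proc.time()[["elapsed"]]
  scal_cfg <- branch_config(input_channels = 3L, input_hw = grid$image_size)
  bin_cfg <- branch_config(input_channels = 1L, input_hw = grid$image_size)
  model <- build_model(alpha = 0.7, scalogram_branch = scal_cfg,
                       binary_branch = bin_cfg, seed = grid$seed)
  features <- compute_branch_features(model, images)
  t2 <- proc.time()[["elapsed"]]
  manifest <- tibble::tibble(record_id = features$record_ids,
                             label = as.character(features$labels))
  list(grid = grid, records = records, images = images, model = model,
       features = features, manifest = manifest,
       timing = c(imaging_s = t1 - t0, features_s = t2 - t1))
}

# Train the dense head on a feature subset and evaluate on another.
# `branch` selects fs / fb / blended-at-alpha; head seed is shared across
# alphas and branches for a given split so that alpha endpoints are exactly
# comparable with single-branch ablations.
run_cell <- function(prep, alpha, split_ids, head_seed, branch = "blend") {
  grid <- prep$grid
  f <- prep$features
  tr <- match(split_ids$train, f$record_ids)
  te <- match(split_ids$test, f$record_ids)
  Xtr <- switch(branch,
    blend = unclass(blend(f$fs[tr, , drop = FALSE], f$fb[tr, , drop = FALSE],
                          blend_config(alpha))),
    scalogram = f$fs[tr, , drop = FALSE],
    binary = f$fb[tr, , drop = FALSE])
  Xte <- switch(branch,
    blend = unclass(blend(f$fs[te, , drop = FALSE], f$fb[te, , drop = FALSE],
                          blend_config(alpha))),
    scalogram = f$fs[te, , drop = FALSE],
    binary = f$fb[te, , drop = FALSE])
  ytr <- f$labels[tr]; yte <- f$labels[te]
  cfg <- train_config(epochs = grid$epochs, batch_size = grid$batch_size,
                      seed = head_seed)
  counts <- table(ytr)
  cw <- class_weights(stats::setNames(as.numeric(counts), names(counts)))
  w <- as.numeric(cw[as.character(ytr)])
  t0 <- proc.time()[["elapsed"]]
  fit <- train_head_adam(Xtr, ytr, cfg, w,
                         dense_units = prep$model$dense_units)
  P <- head_predict(fit$head, Xte)
  wall <- proc.time()[["elapsed"]] - t0
  pred <- factor(ECG_CLASSES[max.col(P, ties.method = "first")],
                 levels = ECG_CLASSES)
  ev <- eval_result(yte, pred, wall)
  ev
}

split_seed <- function(grid, frac) derive_seed(grid$seed, 100 + round(frac * 100))
head_seed <- function(grid, frac) derive_seed(grid$seed, 500 + round(frac * 100))

#' Single-branch ablation
#'
#' Trains and evaluates the scalogram-only and binary-only models (no
#' blending) at one split ratio, with the same branch initialization and
#' head seed the alpha sweep uses — so the sweep's alpha = 1 and alpha = 0
#' cells reproduce these rows exactly.
#'
#' @param grid An [experiment_grid()].
#' @param prep Optional [prepare_experiment()] cache (built if missing).
#' @param split Train fraction (default 0.7).
#' @return Tibble with columns `arch`, `split`, `accuracy`, `wall_time_s`.
#' @export
run_ablation <- function(grid, prep = NULL, split = 0.7) {
  prep <- prep %||% prepare_experiment(grid)
  ids <- stratified_split(prep$manifest, split, split_seed(grid, split))
  hs <- head_seed(grid, split)
  rows <- purrr::map(c(scalogram = "scalogram", binary = "binary"), function(br) {
    ev <- run_cell(prep, alpha = NA, split_ids = ids, head_seed = hs, branch = br)
    tibble::tibble(arch = paste0(br, "_only"), split = split,
                   accuracy = ev$accuracy, wall_time_s = ev$wall_time_s)
  })
  dplyr::bind_rows(rows)
}

#' Sweep blending proportion x split ratio
#'
#' One dense-head cell per (alpha, split): the blended features are retrained
#' and evaluated for each alpha; the stratified split is fixed per split
#' ratio (not re-randomized per alpha), so rows within a split ratio are
#' directly comparable.
#'
#' @param grid An [experiment_grid()].
#' @param prep Optional [prepare_experiment()] cache.
#' @return Tibble of class `alpha_sweep` with columns `alpha`, `split`,
#'   `accuracy`, `wall_time_s`; attribute `best` holds the best row per
#'   split.
#' @export
run_alpha_sweep <- function(grid, prep = NULL) {
  prep <- prep %||% prepare_experiment(grid)
  rows <- list()
  for (frac in grid$splits) {
    ids <- stratified_split(prep$manifest, frac, split_seed(grid, frac))
    hs <- head_seed(grid, frac)
    for (a in grid$alphas) {
      ev <- run_cell(prep, alpha = a, split_ids = ids, head_seed = hs)
      rows[[length(rows) + 1]] <-
        tibble::tibble(alpha = a, split = frac, accuracy = ev$accuracy,
                       wall_time_s = ev$wall_time_s)
    }
  }
  out <- dplyr::bind_rows(rows)
  best <- dplyr::slice_max(dplyr::group_by(out, .data$split), .data$accuracy,
                           n = 1, with_ties = FALSE)
  attr(out, "best") <- dplyr::ungroup(best)
  class(out) <- c("alpha_sweep", class(out))
  out
}

#' Plot an alpha sweep
#'
#' @param object An `alpha_sweep` from [run_alpha_sweep()].
#' @param ... Unused.
#' @return A ggplot of accuracy against alpha, one line per split ratio.
#' @export
autoplot.alpha_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$alpha, y = .data$accuracy,
                               colour = factor(.data$split),
                               group = factor(.data$split))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "test accuracy",
                  colour = "train fraction") +
    ggplot2::theme_minimal()
}

#' Sweep blending proportion x classical ML head
#'
#' Branch features come from the cached (fixed) extractors; for each
#' (alpha, head) cell the blended training features are fitted with the head
#' and evaluated on the held-out set. Split ratio is fixed (default 70:30).
#'
#' @param grid An [experiment_grid()].
#' @param prep Optional [prepare_experiment()] cache.
#' @param split Train fraction (default 0.7).
#' @return Tibble with columns `alpha`, `head`, `accuracy`, `wall_time_s`.
#' @export
run_ml_sweep <- function(grid, prep = NULL, split = 0.7) {
  prep <- prep %||% prepare_experiment(grid)
  ids <- stratified_split(prep$manifest, split, split_seed(grid, split))
  f <- prep$features
  tr <- match(ids$train, f$record_ids)
  te <- match(ids$test, f$record_ids)
  rows <- list()
  for (a in grid$alphas) {
    Xtr <- unclass(blend(f$fs[tr, , drop = FALSE], f$fb[tr, , drop = FALSE],
                         blend_config(a)))
    Xte <- unclass(blend(f$fs[te, , drop = FALSE], f$fb[te, , drop = FALSE],
                         blend_config(a)))
    for (h in grid$heads) {
      spec <- ml_head_spec(h, seed = derive_seed(grid$seed, 900))
      t0 <- proc.time()[["elapsed"]]
      head_fit <- fit_head(Xtr, f$labels[tr], spec)
      pred <- predict_head(head_fit, Xte)$.pred
      wall <- proc.time()[["elapsed"]] - t0
      ev <- eval_result(f$labels[te], pred, wall)
      rows[[length(rows) + 1]] <-
        tibble::tibble(alpha = a, head = h, accuracy = ev$accuracy,
                       wall_time_s = ev$wall_time_s)
    }
  }
  dplyr::bind_rows(rows)
}

#' Stratified k-fold cross-validation of the blended model
#'
#' Trains the dense head on each fold's training portion (blended at
#' `alpha`) and evaluates on the held-out fold. Reports per-fold accuracies
#' plus their mean and standard deviation.
#'
#' @param grid An [experiment_grid()].
#' @param k Number of folds (default 5).
#' @param alpha Blending proportion (default 0.7).
#' @param prep Optional [prepare_experiment()] cache.
#' @return Tibble with one row per fold (`fold`, `accuracy`, `n_test`,
#'   `wall_time_s`); attributes `mean` and `sd` summarize the accuracies.
#' @export
run_cv <- function(grid, k = 5, alpha = 0.7, prep = NULL) {
  prep <- prep %||% prepare_experiment(grid)
  folds <- stratified_kfold(prep$manifest, k = k, seed = derive_seed(grid$seed, 700))
  rows <- purrr::imap(folds, function(fold, i) {
    ev <- run_cell(prep, alpha = alpha, split_ids = fold,
                   head_seed = derive_seed(grid$seed, 800 + i))
    tibble::tibble(fold = i, accuracy = ev$accuracy, n_test = ev$n,
                   wall_time_s = ev$wall_time_s)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean") <- mean(out$accuracy)
  attr(out, "sd") <- stats::sd(out$accuracy)
  out
}

#' Lay an alpha sweep out as a table of accuracies
#'
#' Rows are alpha values, columns are split ratios — the layout of the
#' study's sweep tables.
#'
#' @param sweep Result of [run_alpha_sweep()].
#' @return Wide tibble, one row per alpha.
#' @export
sweep_table <- function(sweep) {
  tidyr::pivot_wider(tibble::as_tibble(sweep)[c("alpha", "split", "accuracy")],
                     names_from = "split", values_from = "accuracy",
                     names_prefix = "train_")
}
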