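#' Configuration of one convolutional branch
#'
#' Each branch is a stack of (3x3 convolution, ReLU, 2x2 max-pool) blocks.
#' The default — three blocks with 16, 32 and 64 filters and dropout 0.25
#' applied to the final features during head training — pools a 227x227
#' input down to a compact 26x26x64 map while staying CPU-friendly.
#'
#' @param filters Integer vector, one entry per block (default
#'   `c(16, 32, 64)`).
#' @param kernel Convolution kernel side (default 3).
#' @param pool Max-pool side (default 2).
#' @param dropout Dropout rate in `[0, 1)` applied to the branch output
#'   during training (default 0.25).
#' @param input_channels 3 for the RGB scalogram branch, 1 for the binary
#'   branch.
#' @param input_hw Input image side length (default 227).
#' @return Object of class `branch_config`.
#' @export
branch_config <- function(filters = c(16L, 32L, 64L), kernel = 3L, pool = 2L,
                          dropout = 0.25, input_channels = 3L, input_hw = 227L) {
  assert_that(length(filters) >= 1 && all(filters >= 1), "need >= 1 conv block")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), dropout = dropout,
                 input_channels = as.integer(input_channels),
                 input_hw = as.integer(input_hw)),
            class = "branch_config")
}

#' Blending configuration
#'
#' Holds the blending proportion alpha of the feature fusion
#' `F = alpha * F_S + (1 - alpha) * F_B`, where `F_S` comes from the
#' scalogram branch and `F_B` from the binary branch. `alpha = 1` uses the
#' scalogram features alone, `alpha = 0` the binary features alone.
#'
#' @param alpha Real in `[0, 1]`.
#' @return Object of class `blend_config`.
#' @export
blend_config <- function(alpha) {
  assert_that(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0 && alpha <= 1,
              "alpha must be a single value in [0, 1]")
  structure(list(alpha = alpha), class = "blend_config")
}

# Output (h, w, channels) after the conv/pool stack.
branch_output_shape <- function(cfg) {
  h <- cfg$input_hw
  for (f in cfg$filters) {
    h <- h - cfg$kernel + 1L  # valid convolution
    h <- h %/% cfg$pool
  }
  c(h, h, cfg$filters[length(cfg$filters)])
}

he_uniform <- function(fan_in, n_out) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(fan_in * n_out, -lim, lim), fan_in, n_out)
}

init_branch_weights <- function(cfg, seed) {
  withr::with_seed(seed, {
    in_ch <- cfg$input_channels
    lapply(cfg$filters, function(f) {
      W <- he_uniform(cfg$kernel^2 * in_ch, f)
      in_ch <<- f
      W
    })
  })
}

#' Build the dual-branch alpha-blending classifier
#'
#' Two parallel convolutional feature extractors (an RGB scalogram branch
#' and a single-channel binary branch) whose pooled feature maps are fused
#' by alpha blending and classified by a softmax head. Branch filters are
#' drawn once from a seeded He-uniform distribution and remain fixed; the
#' head is the trainable part (see [train_model()]). Both branches must
#' produce identical output shapes — construction fails fast otherwise.
#'
#' @param alpha Blending proportion (see [blend_config()]).
#' @param scalogram_branch,binary_branch [branch_config()]s; defaults match
#'   227x227 RGB / binary inputs.
#' @param dense_units Integer vector of hidden ReLU layer sizes in the head
#'   (default one 256-unit layer before the softmax; `integer(0)` gives a
#'   plain softmax layer).
#' @param seed Experiment seed; branch and head sub-seeds are derived from
#'   it, so two models built with the same seed are identical.
#' @return Object of class `ecgblend_model`.
#' @export
build_model <- function(alpha = 0.7,
                        scalogram_branch = branch_config(input_channels = 3L),
                        binary_branch = branch_config(input_channels = 1L),
                        dense_units = 256L,
                        seed = 1) {
  shp_s <- branch_output_shape(scalogram_branch)
  shp_b <- branch_output_shape(binary_branch)
  assert_that(identical(shp_s, shp_b),
              "branch output shapes differ: scalogram ",
              paste(shp_s, collapse = "x"), " vs binary ",
              paste(shp_b, collapse = "x"))
  structure(list(
    blend = blend_config(alpha),
    branches = list(
      scalogram = list(cfg = scalogram_branch,
                       weights = init_branch_weights(scalogram_branch,
                                                     derive_seed(seed, 1))),
      binary = list(cfg = binary_branch,
                    weights = init_branch_weights(binary_branch,
                                                  derive_seed(seed, 2)))
    ),
    output_shape = shp_s,
    n_features = prod(shp_s),
    dense_units = as.integer(dense_units),
    head = NULL,   # untrained: forward() uses a zero head (uniform softmax)
    seed = as.integer(seed)
  ), class = "ecgblend_model")
}

#' @export
print.ecgblend_model <- function(x, ...) {
  cat(sprintf("<ecgblend_model> alpha=%.2f, branch output %s (%d features), head %s\n",
              x$blend$alpha, paste(x$output_shape, collapse = "x"), x$n_features,
              if (is.null(x$head)) "untrained" else "trained"))
  invisible(x)
}

# im2col index cache: building the gather index for a given (H, W, C, k) is
# the expensive part, and shapes repeat across a dataset.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "_")
  idx <- .im2col_cache[[key]]
  if (is.null(idx)) {
    oh <- H - k + 1L; ow <- W - k + 1L
    pos <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * H, "+"))
    offs <- as.vector(outer(
      as.vector(outer(0:(k - 1L), (0:(k - 1L)) * H, "+")),
      (seq_len(C) - 1L) * H * W, "+"))
    idx <- outer(pos, offs, "+")
    .im2col_cache[[key]] <- idx
  }
  idx
}

# Forward pass of one branch: valid 3x3 conv (im2col + GEMM), ReLU, 2x2
# max-pool, repeated per block. x is an (H, W, C) numeric array in [0, 1].
branch_forward <- function(branch, x) {
  cfg <- branch$cfg
  dims <- dim(x)
  assert_that(length(dims) == 3 && dims[1] == cfg$input_hw &&
                dims[2] == cfg$input_hw && dims[3] == cfg$input_channels,
              "branch input shape mismatch: got ", paste(dims, collapse = "x"),
              ", expected ", cfg$input_hw, "x", cfg$input_hw, "x", cfg$input_channels)
  k <- cfg$kernel
  for (l in seq_along(branch$weights)) {
    H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
    idx <- im2col_index(H, W, C, k)
    cols <- matrix(x[idx], nrow = nrow(idx))
    out <- cols %*% branch$weights[[l]]
    out[out < 0] <- 0
    oh <- H - k + 1L; ow <- W - k + 1L
    x <- array(out, dim = c(oh, ow, ncol(out)))
    # 2x2 max-pool, floor semantics
    hp <- oh %/% cfg$pool; wp <- ow %/% cfg$pool
    i1 <- seq(1L, by = 2L, length.out = hp)
    j1 <- seq(1L, by = 2L, length.out = wp)
    x <- pmax(x[i1, j1, , drop = FALSE],      x[i1 + 1L, j1, , drop = FALSE],
              x[i1, j1 + 1L, , drop = FALSE], x[i1 + 1L, j1 + 1L, , drop = FALSE])
  }
  x
}

# Convert stored images to branch input arrays in [0, 1].
scalogram_input <- function(img) array(unclass(img) / 255, dim = dim(img))
binary_input <- function(img) array(as.numeric(unclass(img)), dim = c(dim(img), 1L))

#' Alpha-blend two feature maps
#'
#' Elementwise convex combination `F = alpha * fs + (1 - alpha) * fb` of the
#' scalogram-branch and binary-branch feature maps. The two maps must be
#' shape-matched; the result records the blending proportion used.
#'
#' @param fs,fb Numeric arrays (or vectors) of identical shape: the
#'   scalogram-branch and binary-branch features.
#' @param cfg A [blend_config()] (or a bare alpha in `[0, 1]`).
#' @return Array of the same shape with attributes `source = "blended"` and
#'   `alpha`.
#' @examples
#' blend(matrix(c(1, 0, 0, 1), 2), matrix(c(0, 2, 2, 0), 2), blend_config(0.7))
#' @export
blend <- function(fs, fb, cfg) {
  if (is.numeric(cfg)) cfg <- blend_config(cfg)
  assert_that(inherits(cfg, "blend_config"), "cfg must be a blend_config")
  ds <- dim(fs) %||% length(fs)
  db <- dim(fb) %||% length(fb)
  assert_that(identical(ds, db),
              "feature shapes differ: ", paste(ds, collapse = "x"),
              " vs ", paste(db, collapse = "x"))
  out <- cfg$alpha * unclass(fs) + (1 - cfg$alpha) * unclass(fb)
  attr(out, "source") <- "blended"
  attr(out, "alpha") <- cfg$alpha
  out
}

#' Per-branch feature matrices for a set of images
#'
#' Runs every image through a branch and flattens the pooled maps into rows.
#' This is the alpha-independent half of the pipeline: sweeps over alpha
#' reuse these matrices unchanged.
#'
#' @param model An [build_model()] object.
#' @param images List from [compute_images()].
#' @return List with `fs` and `fb` (`n x n_features` matrices) and `labels`
#'   (factor over the three classes).
#' @export
compute_branch_features <- function(model, images) {
  assert_that(length(images) > 0, "empty image list")
  n <- length(images)
  fs <- matrix(0, n, model$n_features)
  fb <- matrix(0, n, model$n_features)
  for (i in seq_len(n)) {
    fs[i, ] <- as.numeric(branch_forward(model$branches$scalogram,
                                         scalogram_input(images[[i]]$scalogram)))
    fb[i, ] <- as.numeric(branch_forward(model$branches$binary,
                                         binary_input(images[[i]]$binary)))
  }
  labels <- as_class_factor(vapply(images, `[[`, "", "label"))
  list(fs = fs, fb = fb, labels = labels,
       record_ids = vapply(images, `[[`, "", "record_id"))
}

#' Extract the blended feature table
#'
#' Blends the two branch feature matrices at the model's (or a supplied)
#' alpha and returns a tidy table: one row per sample, a `label` column and
#' flattened features `f0, f1, ...`. Because the blend is linear and applied
#' before any head nonlinearity, the alpha = 0.5 table is exactly the mean
#' of the alpha = 0 and alpha = 1 tables.
#'
#' @param model An [build_model()] object.
#' @param images List from [compute_images()], or a precomputed
#'   [compute_branch_features()] result (recommended inside sweeps).
#' @param cfg Optional [blend_config()] overriding the model's alpha.
#' @return Tibble with columns `label`, `f0` ... `f{N-1}`.
#' @export
extract_blended_features <- function(model, images, cfg = NULL) {
  cfg <- cfg %||% model$blend
  if (is.numeric(cfg)) cfg <- blend_config(cfg)
  feats <- if (is.list(images) && !is.null(images$fs)) images
           else compute_branch_features(model, images)
  assert_that(nrow(feats$fs) > 0, "empty dataset")
  X <- blend(feats$fs, feats$fb, cfg)
  colnames(X) <- paste0("f", seq_len(ncol(X)) - 1L)
  dplyr::bind_cols(tibble::tibble(label = feats$labels),
                   tibble::as_tibble(unclass(X)))
}

# Head prediction on a feature matrix. A NULL head acts as an all-zero
# softmax layer (uniform probabilities).
head_predict <- function(head, X, n_classes = 3L) {
  if (is.null(head)) {
    return(matrix(1 / n_classes, nrow(X), n_classes,
                  dimnames = list(NULL, ECG_CLASSES)))
  }
  Z <- sweep(sweep(X, 2, head$mu, "-"), 2, head$sd, "/")
  A <- Z
  if (length(head$hidden) > 0) {
    for (l in seq_along(head$hidden)) {
      A <- A %*% head$hidden[[l]]$W
      A <- sweep(A, 2, head$hidden[[l]]$b, "+")
      A[A < 0] <- 0
    }
  }
  logits <- sweep(A %*% head$W, 2, head$b, "+")
  p <- softmax_rows(logits)
  colnames(p) <- ECG_CLASSES
  p
}

#' Forward pass: images to class probabilities
#'
#' Runs one scalogram/binary image pair through both branches, blends the
#' feature maps at the model's alpha, and applies the softmax head. An
#' untrained model (zero-initialized head) returns uniform probabilities.
#'
#' @param model An [build_model()] object.
#' @param scalogram A `scalogram_image`.
#' @param binary The paired `binary_image`.
#' @return Named numeric vector of 3 class probabilities (sums to 1).
#' @export
forward <- function(model, scalogram, binary) {
  fs <- branch_forward(model$branches$scalogram, scalogram_input(scalogram))
  fb <- branch_forward(model$branches$binary, binary_input(binary))
  x <- matrix(as.numeric(blend(fs, fb, model$blend)), nrow = 1)
  p <- head_predict(model$head, x)
  stats::setNames(as.numeric(p[1, ]), ECG_CLASSES)
}

#' Predict class probabilities for a set of images
#'
#' @param object An [build_model()] object (trained or not).
#' @param images List from [compute_images()], or a
#'   [compute_branch_features()] result.
#' @param ... Unused.
#' @return Tibble with `record_id`, per-class probability columns, and
#'   `.pred` (the argmax class).
#' @export
predict.ecgblend_model <- function(object, images, ...) {
  feats <- if (is.list(images) && !is.null(images$fs)) images
           else compute_branch_features(object, images)
  X <- blend(feats$fs, feats$fb, object$blend)
  p <- head_predict(object$head, unclass(X))
  tibble::tibble(record_id = feats$record_ids,
                 ARR = p[, 1], CHF = p[, 2], NSR = p[, 3],
                 .pred = factor(ECG_CLASSES[max.col(p, ties.method = "first")],
                                levels = ECG_CLASSES))
}
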