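#' Mean activation map of a set of feature maps
#'
#' Elementwise mean over samples and channels of (H, W, C) feature arrays:
#' a single H x W heat matrix showing where, on average, the blended
#' representation is active.
#'
#' @param maps Nonempty list of numeric arrays, all the same shape, each
#'   `(H, W)` or `(H, W, C)`.
#' @return H x W numeric matrix.
#' @export
mean_activation_map <- function(maps) {
  assert_that(is.list(maps) && length(maps) > 0, "empty feature-map list")
  shapes <- lapply(maps, dim)
  assert_that(all(vapply(shapes, identical, TRUE, shapes[[1]])),
              "all maps must share one shape")
  acc <- NULL
  for (m in maps) {
    m <- unclass(m)
    hw <- if (length(dim(m)) == 3) apply(m, c(1, 2), mean) else m
    acc <- if (is.null(acc)) hw else acc + hw
  }
  acc / length(maps)
}

#' Within-cluster sum of squares
#'
#' \eqn{\sum_c \sum_{i \in c} \lVert x_i - \bar{x}_c \rVert^2} with
#' per-cluster mean centroids. Zero iff every cluster's members coincide.
#' Translation-invariant; scales as \eqn{s^2} under coordinate scaling by
#' \eqn{s}.
#'
#' @param coords Numeric matrix, one row per point (typically n x 2
#'   embedding coordinates).
#' @param cluster_labels Cluster assignment per row; every named cluster
#'   must be nonempty.
#' @return Nonnegative scalar.
#' @examples
#' wcss(rbind(c(0, 0), c(2, 0)), c("a", "a"))  # centroid (1,0): 1 + 1 = 2
#' @export
wcss <- function(coords, cluster_labels) {
  coords <- as.matrix(coords)
  assert_that(nrow(coords) == length(cluster_labels),
              "coords and cluster_labels lengths differ")
  assert_that(nrow(coords) > 0, "empty coordinate set")
  f <- factor(cluster_labels)
  assert_that(all(table(f) > 0), "empty cluster")
  centroids <- rowsum(coords, f) / as.vector(table(f))
  sum((coords - centroids[as.integer(f), , drop = FALSE])^2)
}

#' t-SNE embedding of a blended feature table
#'
#' Embeds the features in 2-D with t-SNE (seeded, so repeated calls agree)
#' and computes the within-cluster sum of squares of the embedding using the
#' true class labels as clusters — the per-alpha compactness diagnostic.
#' Smaller WCSS means the classes form tighter clusters in feature space.
#'
#' @param features Tibble from [extract_blended_features()] (with a `label`
#'   column) or a numeric matrix plus `labels`.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (default 30); requires
#'   `n > 3 * perplexity`.
#' @param labels Labels when `features` is a bare matrix.
#' @param max_iter t-SNE iterations (default 1000).
#' @return Object of class `tsne_embedding`: tibble with `x`, `y`, `label`
#'   and attributes `wcss`, `alpha` (if the features carry one),
#'   `perplexity`.
#' @export
embed_tsne <- function(features, seed = 1, perplexity = 30, labels = NULL,
                       max_iter = 1000) {
  if (is.data.frame(features)) {
    labels <- labels %||% features$label
    X <- as.matrix(features[setdiff(names(features), "label")])
  } else {
    X <- as.matrix(features)
  }
  assert_that(!is.null(labels), "labels are required")
  n <- nrow(X)
  assert_that(n > 3 * perplexity,
              "too few points (", n, ") for perplexity ", perplexity,
              " (need n > 3 * perplexity)")
  emb <- withr::with_seed(as.integer(seed),
    Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, max_iter = max_iter,
                 check_duplicates = FALSE, pca = TRUE, verbose = FALSE))
  coords <- emb$Y
  out <- tibble::tibble(x = coords[, 1], y = coords[, 2],
                        label = as_class_factor(labels))
  attr(out, "wcss") <- wcss(coords, labels)
  attr(out, "perplexity") <- perplexity
  attr(out, "alpha") <- attr(features, "alpha")
  class(out) <- c("tsne_embedding", class(out))
  out
}

#' Plot a t-SNE embedding
#'
#' @param object A `tsne_embedding` from [embed_tsne()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tsne_embedding <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = sprintf("t-SNE of blended features (WCSS = %.2f)",
                                  attr(object, "wcss")),
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a mean activation map
#'
#' @param heat H x W matrix from [mean_activation_map()].
#' @return A ggplot raster of the map (row 1 at the top, matching the
#'   highest-frequency-first image convention).
#' @export
plot_activation_map <- function(heat) {
  df <- tidyr::expand_grid(row = seq_len(nrow(heat)), col = seq_len(ncol(heat)))
  df$value <- as.vector(t(heat))[(df$row - 1) * ncol(heat) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "activation") +
    ggplot2::labs(x = "time", y = "scale") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
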