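#' Jet colormap lookup table
#'
#' The classic blue-cyan-yellow-red rainbow map, returned as an `n x 3`
#' matrix of RGB values in `[0, 1]`.
#'
#' @param n Number of entries (default 256).
#' @return `n x 3` numeric matrix.
#' @keywords internal
jet_colormap <- function(n = 256) {
  u <- seq(0, 1, length.out = n)
  interp <- function(x) pmin(pmax(1.5 - abs(4 * x), 0), 1)
  cbind(interp(u - 0.75), interp(u - 0.5), interp(u - 0.25))
}

get_colormap <- function(name, n = 256) {
  switch(name,
         jet = jet_colormap(n),
         gray = ,
         grey = cbind(seq(0, 1, length.out = n), seq(0, 1, length.out = n),
                      seq(0, 1, length.out = n)),
         stop_ecg("unknown colormap '", name, "'"))
}

#' Render CWT coefficients as a scalogram image
#'
#' The coefficient magnitudes are min-max scaled to `[0, 1]` globally per
#' image (no log transform by default: intensity represents magnitude),
#' mapped through a colormap to RGB, and bilinearly resized to a square
#' image. Row 1 of the result is the highest-frequency scale; columns run
#' left to right in time. An all-zero coefficient matrix renders uniformly in
#' the colormap's zero color rather than dividing by zero.
#'
#' @param coeffs Complex or numeric matrix from [cwt_coefficients()].
#' @param colormap Colormap name (`"jet"`, the default, or `"gray"`).
#' @param size Output side length in pixels (default 227). `NULL` skips the
#'   resize, returning the native `n_scales x L` rendering (useful for
#'   inspecting the raw grid).
#' @param log_magnitude If `TRUE`, scale `log1p(|W|)` instead of `|W|`.
#' @return Integer array `size x size x 3` with values in 0..255, of class
#'   `scalogram_image` (attribute `colormap` records the map used).
#' @export
render_scalogram <- function(coeffs, colormap = "jet", size = 227L,
                             log_magnitude = FALSE) {
  assert_that(is.matrix(coeffs) && length(coeffs) > 0, "coeffs must be a nonempty matrix")
  mag <- Mod(coeffs)
  if (log_magnitude) mag <- log1p(mag)
  lo <- min(mag); hi <- max(mag)
  norm <- if (hi > lo) (mag - lo) / (hi - lo) else matrix(0, nrow(mag), ncol(mag))
  lut <- get_colormap(colormap)
  idx <- pmin(floor(norm * 256) + 1L, 256L)
  rgb <- array(0, dim = c(nrow(mag), ncol(mag), 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(lut[idx, ch], nrow(mag), ncol(mag))
  if (!is.null(size)) {
    res <- array(0, dim = c(size, size, 3))
    for (ch in 1:3) {
      res[, , ch] <- EBImage::resize(EBImage::Image(rgb[, , ch]),
                                     w = size, h = size, filter = "bilinear")@.Data
    }
    rgb <- res
  }
  px <- array(as.integer(pmin(pmax(round(rgb * 255), 0), 255)), dim = dim(rgb))
  structure(px, class = "scalogram_image", colormap = colormap)
}

#' Convert a scalogram image to grayscale
#'
#' Standard luma weights: `gray = round(0.299 R + 0.587 G + 0.114 B)`,
#' clipped to 0..255.
#'
#' @param img A `scalogram_image` (or any `H x W x 3` array in 0..255).
#' @return Integer matrix of class `gray_image`.
#' @export
to_grayscale <- function(img) {
  assert_that(length(dim(img)) == 3 && dim(img)[3] == 3,
              "img must be an H x W x 3 array")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  g <- matrix(as.integer(pmin(pmax(round(g), 0), 255)), nrow(g), ncol(g))
  structure(g, class = "gray_image")
}

#' Otsu's threshold of a grayscale image
#'
#' Exhaustively evaluates the between-class variance of the 256-bin histogram
#' at every candidate threshold `t` (classes `<= t` and `> t`) and returns
#' the maximizer; ties break toward the lowest threshold.
#'
#' @param gray A `gray_image` or integer matrix with values 0..255.
#' @return Integer threshold in 0..254.
#' @export
otsu_threshold <- function(gray) {
  v <- as.integer(gray)
  assert_that(all(v >= 0 & v <= 255), "gray values must lie in 0..255")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  levels <- 0:255
  w0 <- cumsum(h)                    # count of pixels <= t
  m0 <- cumsum(h * levels)           # sum of values <= t
  total <- m0[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m0 / w0
  mu1 <- (total - m0) / w1
  bcv <- ifelse(valid, (w0 / n) * (w1 / n) * (mu0 - mu1)^2, -Inf)
  t <- which.max(bcv) - 1L           # which.max returns the first (lowest) argmax
  as.integer(t)
}

#' Binarize a grayscale image
#'
#' Pixels strictly exceeding the threshold become 1 (white, signal present),
#' all others 0. The default threshold 128 is the conventional midpoint of
#' the 0..255 range; pass `"otsu"` to derive the threshold from the image
#' histogram via [otsu_threshold()].
#'
#' @param img A `gray_image` (or integer matrix 0..255).
#' @param threshold Integer in 0..255, or the string `"otsu"`.
#' @return Integer matrix of class `binary_image` with values in `{0, 1}`;
#'   attribute `threshold_used` records the applied threshold.
#' @export
binarize <- function(img, threshold = 128) {
  assert_that(is.matrix(img), "img must be a matrix")
  if (identical(threshold, "otsu")) {
    thr <- otsu_threshold(img)
    label <- "otsu"
  } else {
    assert_that(is.numeric(threshold) && length(threshold) == 1 &&
                  threshold >= 0 && threshold <= 255,
                "threshold must be in 0..255 or 'otsu'")
    thr <- threshold
    label <- threshold
  }
  b <- matrix(as.integer(unclass(img) > thr), nrow(img), ncol(img))
  structure(b, class = "binary_image", threshold_used = label,
            threshold_value = as.integer(thr))
}

#' Write an image to a PNG file
#'
#' @param img A `scalogram_image`, `gray_image` or `binary_image`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(img, path) {
  x <- unclass(img)
  if (inherits(img, "binary_image")) x <- x * 255L
  png::writePNG(x / 255, path)
  invisible(path)
}

#' Compute the paired image representations of one record
#'
#' Full imaging front end for a single record: cut the segment, z-normalize,
#' CWT, render the RGB scalogram, grayscale it and binarize. The two images
#' returned are the inputs of the two network branches.
#'
#' @param record An [ecg_record()].
#' @param bank A [cwt_filter_bank()] (built for `segment_length` if `NULL`).
#' @param segment_length,offset Passed to [extract_segment()].
#' @param colormap,threshold,image_size Rendering controls; see
#'   [render_scalogram()] and [binarize()].
#' @return List with elements `record_id`, `label`, `scalogram`
#'   (`scalogram_image`), `gray` (`gray_image`) and `binary` (`binary_image`).
#' @export
record_images <- function(record, bank = NULL, segment_length = 1000, offset = 0,
                          colormap = "jet", threshold = 128, image_size = 227L) {
  if (is.null(bank)) {
    bank <- cwt_filter_bank(signal_length = segment_length, fs = record$fs)
  }
  seg <- znormalize(extract_segment(record, length = segment_length, offset = offset))
  W <- cwt_coefficients(seg, bank)
  sc <- render_scalogram(W, colormap = colormap, size = image_size)
  # grayscale for binarization comes from a gray rendering of the same
  # coefficients, so gray level is monotone in |W| and the threshold
  # separates strong time-frequency support from background (a luma of the
  # jet rendering would be non-monotone in magnitude)
  gr <- to_grayscale(render_scalogram(W, colormap = "gray", size = image_size))
  bi <- binarize(gr, threshold = threshold)
  list(record_id = record$record_id, label = record$label,
       scalogram = sc, gray = gr, binary = bi)
}

#' Compute images for a whole dataset
#'
#' Applies [record_images()] to every record, reusing one filter bank. This
#' is the cacheable, alpha-independent part of the pipeline: experiment
#' sweeps image each dataset exactly once.
#'
#' @param records List of [ecg_record()]s.
#' @inheritParams record_images
#' @return List of [record_images()] results, in input order.
#' @export
compute_images <- function(records, segment_length = 1000, offset = 0,
                           colormap = "jet", threshold = 128, image_size = 227L) {
  assert_that(length(records) > 0, "no records supplied")
  bank <- cwt_filter_bank(signal_length = segment_length, fs = records[[1]]$fs)
  purrr::map(records, record_images, bank = bank,
             segment_length = segment_length, offset = offset,
             colormap = colormap, threshold = threshold, image_size = image_size)
}
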