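test_that("constant-magnitude coefficients render as a uniform image", {
  coeffs <- matrix(complex(modulus = 3, argument = 0.3), 20, 50)
  img <- render_scalogram(coeffs, size = 32L)
  expect_equal(dim(img), c(32, 32, 3))
  for (ch in 1:3) expect_equal(length(unique(as.vector(img[, , ch]))), 1)
  # all-zero matrix renders without division by zero, same uniform color
  img0 <- render_scalogram(matrix(0, 20, 50), size = 32L)
  expect_identical(unclass(img0), unclass(img))
})

test_that("the pre-resize argmax pixel gets the colormap's top color", {
  m <- matrix(0.2, 30, 40)
  m[17, 23] <- 5
  img <- render_scalogram(m, size = NULL)
  top <- jet_colormap(256)[256, ] * 255
  expect_equal(as.numeric(img[17, 23, ]), round(top))
  # exactly one pixel region at top color
  is_top <- img[, , 1] == round(top[1]) & img[, , 2] == round(top[2]) &
    img[, , 3] == round(top[3])
  expect_equal(sum(is_top), 1)
})

test_that("rendering is byte-deterministic", {
  withr::local_seed(11)
  coeffs <- matrix(complex(real = rnorm(600), imaginary = rnorm(600)), 20, 30)
  a <- render_scalogram(coeffs)
  b <- render_scalogram(coeffs)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_image_png(a, f1); write_image_png(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("grayscale conversion uses rounded luma weights", {
  white <- array(255L, dim = c(4, 4, 3))
  expect_true(all(to_grayscale(white) == 255))
  red <- array(0L, dim = c(4, 4, 3)); red[, , 1] <- 255L
  expect_true(all(to_grayscale(red) == 76))  # round(0.299 * 255)
  gray_in <- array(rep(matrix(0:15, 4, 4), 3), dim = c(4, 4, 3))
  expect_equal(unclass(to_grayscale(gray_in)), matrix(0:15, 4, 4),
               ignore_attr = TRUE)
})

test_that("fixed-threshold binarization uses strict inequality", {
  g <- matrix(c(100L, 128L, 129L, 0L), 2, 2)
  b <- binarize(g, 128)
  expect_equal(as.vector(unclass(b)), c(0L, 0L, 1L, 0L))
  expect_true(all(unclass(b) %in% c(0L, 1L)))
  expect_equal(attr(b, "threshold_value"), 128L)
  expect_true(all(binarize(matrix(0L, 5, 5), 128) == 0))
  expect_error(binarize(g, 300), "0..255")
})

test_that("binarization is idempotent when 1 is mapped back to 255", {
  withr::local_seed(3)
  g <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  b1 <- binarize(g, 128)
  b2 <- binarize(matrix(unclass(b1) * 255L, 20, 20), 128)
  expect_identical(unclass(b2), unclass(b1))
})

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  # independent oracle: brute-force double loop over thresholds and classes
  otsu_brute <- function(v) {
    best_t <- 0L; best_var <- -Inf
    n <- length(v)
    for (t in 0:255) {
      lo <- v[v <= t]; hi <- v[v > t]
      if (length(lo) == 0 || length(hi) == 0) next
      bc <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
      if (bc > best_var + 1e-12) { best_var <- bc; best_t <- t }
    }
    best_t
  }
  withr::local_seed(21)
  for (i in 1:20) {
    v <- switch(i %% 4 + 1,
      sample(0:255, 500, replace = TRUE),
      c(sample(0:80, 300, replace = TRUE), sample(170:255, 200, replace = TRUE)),
      rbinom(400, 255, 0.3),
      pmin(pmax(round(c(rnorm(250, 60, 20), rnorm(250, 190, 25))), 0), 255))
    g <- matrix(as.integer(v), ncol = 10)
    expect_identical(otsu_threshold(g), as.integer(otsu_brute(as.integer(g))))
  }
  # binarize with the otsu sentinel applies the found threshold
  g <- matrix(as.integer(c(rep(10, 200), rep(200, 200))), 20, 20)
  b <- binarize(g, "otsu")
  expect_identical(attr(b, "threshold_used"), "otsu")
  expect_equal(sum(b), 200)
})

test_that("full imaging pipeline is deterministic per record", {
  rec <- generate_dataset(synth_spec(c(ARR = 1, CHF = 1, NSR = 1),
                                     seed = 13, length = 1200))[[1]]
  fb <- cwt_filter_bank(signal_length = 600, fs = 128)
  i1 <- record_images(rec, fb, segment_length = 600, image_size = 64L)
  i2 <- record_images(rec, fb, segment_length = 600, image_size = 64L)
  expect_identical(i1, i2)
  expect_equal(dim(i1$scalogram), c(64, 64, 3))
  expect_equal(dim(i1$binary), c(64, 64))
  expect_true(all(unclass(i1$binary) %in% 0:1))
})
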