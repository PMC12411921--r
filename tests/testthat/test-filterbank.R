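test_that("filter bank scales are geometric and span (0, fs/2]", {
  fb <- cwt_filter_bank(signal_length = 1000, fs = 128)
  expect_gt(length(fb$scales), 2)
  expect_true(all(diff(fb$scales) > 0))
  ratios <- fb$scales[-1] / fb$scales[-length(fb$scales)]
  expect_equal(ratios, rep(2^(1 / 10), length(ratios)), tolerance = 1e-12)
  expect_true(all(fb$frequencies > 0 & fb$frequencies <= 64))
  expect_equal(max(fb$frequencies), 64, tolerance = 1e-9)
  expect_error(cwt_coefficients(rnorm(500), fb), "does not match")
})

test_that("zero signal transforms to exactly zero coefficients", {
  fb <- cwt_filter_bank(signal_length = 256, fs = 128)
  W <- cwt_coefficients(rep(0, 256), fb)
  expect_equal(max(Mod(W)), 0)
})

test_that("ridge of a pure 8 Hz tone lands within one voice step of 8 Hz", {
  fb <- cwt_filter_bank(signal_length = 256, fs = 128)
  x <- sin(2 * pi * 8 * (0:255) / 128)
  W <- cwt_coefficients(x, fb)
  ridge_freq <- fb$frequencies[which.max(rowMeans(Mod(W)))]
  step <- 2^(1 / fb$voices_per_octave)
  expect_gt(ridge_freq, 8 / step)
  expect_lt(ridge_freq, 8 * step)
})

test_that("FFT-convolution coefficients match direct quadrature of the CWT integral", {
  # Independent oracle: the analytic Morlet has the closed time-domain form
  # psi(t) = sqrt(2/pi) exp(i w0 t) exp(-t^2/2); sum x[n] conj(psi((n-b)/a))/a
  # directly discretizes W(a,b) = (1/a) int f(t) psi*((t-b)/a) dt.
  withr::local_seed(42)
  L <- 256
  tt <- (0:(L - 1)) / 128
  x <- sin(2 * pi * (4 + 20 * tt) * tt) + 0.3 * rnorm(L)  # chirp + noise
  fb <- cwt_filter_bank("morlet", signal_length = L, fs = 128)
  W <- cwt_coefficients(x, fb)
  w0 <- 6
  psi <- function(t) sqrt(2 / pi) * exp(-t^2 / 2) * exp(1i * w0 * t)
  n <- 0:(L - 1)
  pts <- list(c(8, 128), c(14, 100), c(20, 128), c(26, 160), c(32, 128))
  for (p in pts) {
    a <- fb$scales[p[1]]; b <- p[2]
    oracle <- sum(x * Conj(psi((n - b) / a)) / a)
    expect_lt(Mod(W[p[1], b + 1] - oracle) / Mod(oracle), 1e-3)
  }
})

test_that("the transform is linear in the signal", {
  fb <- cwt_filter_bank(signal_length = 256, fs = 128)
  withr::local_seed(8)
  x <- rnorm(256); y <- rnorm(256)
  Wx <- cwt_coefficients(x, fb)
  Wy <- cwt_coefficients(y, fb)
  Wxy <- cwt_coefficients(2.5 * x - 1.5 * y, fb)
  expect_lt(max(Mod(Wxy - 2.5 * Wx + 1.5 * Wy)), 1e-9)
})

test_that("coefficients are shift-covariant away from the boundary", {
  fb <- cwt_filter_bank(signal_length = 256, fs = 128)
  withr::local_seed(9)
  x <- rnorm(256)
  k <- 40
  xs <- c(x[(k + 1):256], x[1:k])  # circular shift left by k
  W <- cwt_coefficients(x, fb)
  Ws <- cwt_coefficients(xs, fb)
  # rows below scale 1.2 are truncated at Nyquist (ringing tails); the
  # wavelet kernel is numerically supported within ~20 scales of its center
  for (i in seq_along(fb$scales)) {
    s <- fb$scales[i]
    if (s < 1.2) next
    margin <- ceiling(20 * s)
    cols <- seq_len(256)
    interior <- cols[cols > margin & cols <= 256 - k - margin]
    if (length(interior) < 30) next
    expect_lt(max(Mod(Ws[i, interior] - W[i, interior + k])), 1e-6)
  }
})

test_that("Morse and Morlet banks both peak at the tone frequency", {
  for (fam in c("morse", "morlet")) {
    fb <- cwt_filter_bank(fam, signal_length = 512, fs = 128)
    x <- cos(2 * pi * 12 * (0:511) / 128)
    W <- cwt_coefficients(x, fb)
    ridge <- fb$frequencies[which.max(rowMeans(Mod(W)))]
    expect_equal(log2(ridge / 12), 0, tolerance = 1.01 / fb$voices_per_octave)
  }
})
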