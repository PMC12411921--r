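#' Continuous wavelet transform filter bank
#'
#' Builds the set of analytic wavelets used to turn a 1-D segment into a
#' time-frequency coefficient plane. Two families are supported:
#'
#' * `"morse"` — generalized Morse wavelets parameterized by `gamma` and the
#'   time-bandwidth product \eqn{P^2 = \beta\gamma}. The defaults
#'   (`gamma = 3`, `time_bandwidth = 60`, 10 voices per octave) are the
#'   conventional filter-bank defaults for this family.
#' * `"morlet"` — the analytic Morlet wavelet with center frequency
#'   \eqn{\omega_0 = 6}, which has the closed time-domain form
#'   \eqn{\psi(t) = \sqrt{2/\pi}\, e^{i\omega_0 t} e^{-t^2/2}}.
#'
#' Wavelets are L1-normalized (the `1/a` convention), so an amplitude-A
#' sinusoid yields coefficient magnitude close to A at its scale regardless
#' of scale. Scales are geometric with `voices_per_octave` steps per octave,
#' from the scale whose center frequency is the Nyquist frequency down to a
#' scale whose time support still fits comfortably inside the signal.
#'
#' @param wavelet `"morse"` or `"morlet"`.
#' @param signal_length Length in samples of the segments this bank will
#'   transform.
#' @param fs Sampling rate in Hz.
#' @param voices_per_octave Scales per frequency doubling (default 10).
#' @param gamma,time_bandwidth Morse family parameters (defaults 3 and 60).
#' @param freq_limits Optional `c(fmin, fmax)` in Hz overriding the automatic
#'   frequency range.
#' @return An object of class `cwt_filter_bank` with fields `scales`
#'   (ascending, i.e. descending frequency order is `rev`), `frequencies`
#'   (descending, Hz, aligned with the coefficient rows), `wavelet`, `fs`,
#'   `signal_length`, and the family parameters.
#' @examples
#' fb <- cwt_filter_bank(signal_length = 1000, fs = 128)
#' range(fb$frequencies)
#' @export
cwt_filter_bank <- function(wavelet = c("morse", "morlet"),
                            signal_length, fs,
                            voices_per_octave = 10,
                            gamma = 3, time_bandwidth = 60,
                            freq_limits = NULL) {
  wavelet <- match.arg(wavelet)
  assert_that(signal_length >= 4, "signal_length must be >= 4")
  assert_that(fs > 0, "fs must be > 0")
  assert_that(voices_per_octave >= 1, "voices_per_octave must be >= 1")

  if (wavelet == "morse") {
    assert_that(time_bandwidth > gamma, "time_bandwidth must exceed gamma")
    beta <- time_bandwidth / gamma
    wp <- (beta / gamma)^(1 / gamma)        # peak frequency, rad/sample at scale 1
    sigma_cycles <- sqrt(beta * gamma) / wp  # approx time std at scale 1, samples
  } else {
    beta <- NA_real_
    wp <- 6
    sigma_cycles <- 1
  }

  s_min <- wp / pi                            # center frequency = Nyquist
  s_max <- signal_length / (6 * sigma_cycles) # +-3 time-stds fit in the window
  if (!is.null(freq_limits)) {
    assert_that(length(freq_limits) == 2 && freq_limits[1] < freq_limits[2] &&
                  freq_limits[2] <= fs / 2,
                "freq_limits must be c(fmin, fmax) with fmax <= fs/2")
    # f = wp * fs / (2 pi s)  =>  s = wp * fs / (2 pi f)
    s_min <- wp * fs / (2 * pi * freq_limits[2])
    s_max <- wp * fs / (2 * pi * freq_limits[1])
  }
  assert_that(s_max > s_min * 2^(1 / voices_per_octave),
              "signal too short for this wavelet family")
  n_scales <- floor(voices_per_octave * log2(s_max / s_min)) + 1
  scales <- s_min * 2^((seq_len(n_scales) - 1) / voices_per_octave)
  freqs <- wp * fs / (2 * pi * scales)  # Hz, descending

  structure(list(wavelet = wavelet, scales = scales, frequencies = freqs,
                 voices_per_octave = voices_per_octave,
                 signal_length = as.integer(signal_length), fs = fs,
                 gamma = gamma, beta = beta, time_bandwidth = time_bandwidth,
                 peak_omega = wp),
            class = "cwt_filter_bank")
}

#' @export
print.cwt_filter_bank <- function(x, ...) {
  cat(sprintf("<cwt_filter_bank %s> %d scales, %.2f-%.2f Hz, %d voices/octave, L=%d @ %g Hz\n",
              x$wavelet, length(x$scales), min(x$frequencies), max(x$frequencies),
              x$voices_per_octave, x$signal_length, x$fs))
  invisible(x)
}

# Frequency-domain wavelet evaluated at radian frequencies omega (per-sample),
# already scaled: pass omega * scale. Peak value normalized to 2 (analytic
# convention: only positive frequencies are supported).
wavelet_fourier <- function(bank, omega_scaled) {
  out <- numeric(length(omega_scaled))
  pos <- omega_scaled > 0
  w <- omega_scaled[pos]
  if (bank$wavelet == "morse") {
    beta <- bank$beta; gamma <- bank$gamma; wp <- bank$peak_omega
    out[pos] <- 2 * exp(beta * (log(w) - log(wp)) - (w^gamma - wp^gamma))
  } else {
    out[pos] <- 2 * exp(-((w - bank$peak_omega)^2) / 2)
  }
  out
}

#' Continuous wavelet transform of a segment
#'
#' Computes \eqn{W(a,b) = \frac{1}{a}\int f(t)\, \psi^*\!\big(\frac{t-b}{a}\big)\,dt}
#' for every scale in the bank via FFT convolution: the segment is
#' symmetrically padded by half its length on each side, multiplied in the
#' frequency domain by the conjugate analytic wavelet at each scale, inverted,
#' and cropped back.
#'
#' @param segment An `ecg_segment` (see [extract_segment()]) or a bare
#'   numeric vector.
#' @param bank A [cwt_filter_bank()] whose `signal_length` matches the
#'   segment.
#' @return Complex matrix of dimension `n_scales x signal_length`; row 1 is
#'   the highest-frequency scale (frequencies given by `bank$frequencies`),
#'   columns are time samples.
#' @examples
#' fb <- cwt_filter_bank(signal_length = 256, fs = 128)
#' x <- sin(2 * pi * 8 * (0:255) / 128)
#' W <- cwt_coefficients(x, fb)
#' fb$frequencies[which.max(rowMeans(Mod(W)))]  # ~8 Hz
#' @export
cwt_coefficients <- function(segment, bank) {
  assert_that(inherits(bank, "cwt_filter_bank"), "bank must be a cwt_filter_bank")
  x <- if (inherits(segment, "ecg_segment")) segment$values else as.numeric(segment)
  assert_that(length(x) == bank$signal_length,
              "segment length ", length(x), " does not match bank signal_length ",
              bank$signal_length)
  L <- length(x)
  half <- L %/% 2
  xp <- c(rev(x[seq_len(half)]), x, rev(x[(L - half + 1):L]))
  n <- length(xp)
  X <- fft(xp)
  k <- 0:(n - 1)
  omega <- 2 * pi * k / n
  # analytic wavelets live on (0, pi]; frequencies above Nyquist are the
  # negative-frequency half and get zero response
  omega[omega > pi] <- -1
  out <- matrix(complex(real = 0, imaginary = 0), nrow = length(bank$scales), ncol = L)
  for (i in seq_along(bank$scales)) {
    psi <- wavelet_fourier(bank, omega * bank$scales[i])
    w <- fft(X * Conj(psi), inverse = TRUE) / n
    out[i, ] <- w[(half + 1):(half + L)]
  }
  out
}
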