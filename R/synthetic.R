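#' Parametric P-QRS-T beat templates
#'
#' Beats are sums of Gaussians, one per ECG wave. Three templates are built
#' in: `"normal"` (textbook P-QRS-T), `"wide"` (ectopic-style broad QRS with
#' inverted T, no P wave) and `"narrow"` (reduced-amplitude narrow complex
#' used for the CHF caricature).
#'
#' @param id Template identifier.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector sampling the beat over roughly -0.25..0.4 s.
#' @keywords internal
beat_template <- function(id = c("normal", "wide", "narrow"), fs = 128) {
  id <- match.arg(id)
  waves <- switch(id,
    normal = list(c(-0.18, 0.025, 0.15),   # P
                  c(-0.035, 0.012, -0.12), # Q
                  c(0.00, 0.014, 1.00),    # R
                  c(0.035, 0.012, -0.20),  # S
                  c(0.22, 0.060, 0.30)),   # T
    wide = list(c(0.00, 0.050, 0.90),
                c(0.09, 0.040, -0.45),
                c(0.30, 0.080, -0.25)),
    narrow = list(c(-0.16, 0.020, 0.10),
                  c(-0.030, 0.010, -0.08),
                  c(0.00, 0.010, 0.70),
                  c(0.030, 0.010, -0.14),
                  c(0.18, 0.050, 0.20)))
  t <- seq(-0.25, 0.4, by = 1 / fs)
  y <- rep(0, length(t))
  for (w in waves) y <- y + w[3] * exp(-((t - w[1])^2) / (2 * w[2]^2))
  y
}

default_class_params <- function() {
  list(
    ARR = list(mean_rate_bpm = 85, rate_jitter_cv = 0.30, beat_template = "normal",
               amplitude_envelope = "flat", noise_sd = 0.05, ectopic_prob = 0.25,
               ectopic_every = 3:5),
    CHF = list(mean_rate_bpm = 110, rate_jitter_cv = 0.05, beat_template = "narrow",
               amplitude_envelope = "alternans", noise_sd = 0.05, ectopic_prob = 0),
    NSR = list(mean_rate_bpm = 75, rate_jitter_cv = 0.03, beat_template = "normal",
               amplitude_envelope = "flat", noise_sd = 0.05, ectopic_prob = 0)
  )
}

#' Specification for a synthetic three-class ECG dataset
#'
#' The defaults emulate the public 162-recording three-cohort bundle this
#' package targets: 128 Hz sampling, the 96/30/36 ARR/CHF/NSR imbalance, and
#' class recipes that caricature the clinical signatures — NSR is a regular
#' sinus train, ARR has high RR-interval jitter plus occasional wide ectopic
#' beats, CHF is a fast low-amplitude train with an alternans-like
#' beat-to-beat amplitude envelope. These differences live in time-frequency
#' structure, so they survive the scalogram/binary imaging front end.
#'
#' @param n_per_class Named counts per class (default `c(ARR = 96, CHF = 30,
#'   NSR = 36)`).
#' @param fs Sampling rate in Hz (default 128).
#' @param length Record length in samples (default 2000; must hold at least
#'   one beat).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the spec.
#' @param class_params Per-class recipe list; see `default_class_params`
#'   in the package source for the shape.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = c(ARR = 96, CHF = 30, NSR = 36),
                       fs = 128, length = 2000, seed = 1,
                       class_params = default_class_params()) {
  assert_that(all(ECG_CLASSES %in% names(n_per_class)),
              "n_per_class must name ARR, CHF and NSR")
  n_per_class <- n_per_class[ECG_CLASSES]
  assert_that(all(n_per_class > 0), "all class counts must be > 0")
  assert_that(fs > 0, "fs must be > 0")
  for (p in class_params) {
    assert_that(p$noise_sd >= 0, "noise_sd must be >= 0")
    assert_that(p$rate_jitter_cv >= 0, "rate_jitter_cv must be >= 0")
  }
  # shortest record that can hold one full beat template
  assert_that(length > 0.65 * fs, "record length too short to hold one beat")
  structure(list(n_per_class = n_per_class, fs = fs, length = as.integer(length),
                 seed = as.integer(seed), class_params = class_params),
            class = "synth_spec")
}

# Synthesize one record; consumes the ambient RNG stream.
synth_record <- function(record_id, label, params, fs, len) {
  dur <- len / fs
  mean_rr <- 60 / params$mean_rate_bpm
  n_beats <- ceiling(dur / mean_rr) + 4
  rr <- mean_rr * pmax(0.4, rnorm(n_beats, 1, params$rate_jitter_cv))
  beat_times <- cumsum(c(runif(1, 0, mean_rr), rr))
  beat_times <- beat_times[beat_times < dur + 0.3]
  y <- rep(0, len)
  tmpl_main <- beat_template(params$beat_template, fs)
  tmpl_ecto <- beat_template("wide", fs)
  half <- floor(0.25 * fs)  # template starts 0.25 s before the R peak
  # persistent ectopy: every m-th beat is wide (trigeminy-like), m drawn per
  # record, so the arrhythmic morphology is present in any analysis window
  ect_every <- if (!is.null(params$ectopic_every)) {
    if (length(params$ectopic_every) > 1) sample(params$ectopic_every, 1)
    else params$ectopic_every
  } else NA
  for (b in seq_along(beat_times)) {
    ect <- if (!is.na(ect_every)) (b %% ect_every == 0)
           else params$ectopic_prob > 0 && runif(1) < params$ectopic_prob
    tmpl <- if (ect) tmpl_ecto else tmpl_main
    amp <- switch(params$amplitude_envelope,
                  flat = 1,
                  alternans = if (b %% 2 == 0) 0.55 else 1,
                  1)
    i0 <- round(beat_times[b] * fs) - half
    idx <- seq_along(tmpl) + i0
    keep <- idx >= 1 & idx <= len
    y[idx[keep]] <- y[idx[keep]] + amp * tmpl[keep]
  }
  if (params$noise_sd > 0) y <- y + rnorm(len, 0, params$noise_sd)
  ecg_record(record_id, y, fs = fs, label = label)
}

#' Generate a labeled synthetic ECG dataset
#'
#' Deterministic given the spec (same spec + seed gives bitwise-identical
#' records): one global RNG stream, records generated in fixed
#' (class, index) order.
#'
#' @param spec A [synth_spec()].
#' @return List of [ecg_record()]s ordered by (class, index).
#' @examples
#' recs <- generate_dataset(synth_spec(c(ARR = 3, CHF = 2, NSR = 2), seed = 7))
#' table(vapply(recs, `[[`, "", "label"))
#' @export
generate_dataset <- function(spec) {
  assert_that(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  withr::with_seed(spec$seed, {
    out <- list()
    for (cls in ECG_CLASSES) {
      n <- spec$n_per_class[[cls]]
      for (i in seq_len(n)) {
        id <- sprintf("%s_%03d", cls, i)
        out[[id]] <- synth_record(id, cls, spec$class_params[[cls]],
                                  spec$fs, spec$length)
      }
    }
    unname(out)
  })
}

#' Generate a modality-pure probe dataset
#'
#' Diagnostic datasets in which the class signal is confined to a single
#' image modality, used to verify that the blending proportion genuinely
#' gates which modality the classifier can exploit.
#'
#' * `"scalogram_only"`: all records share class-free support — jittered
#'   broadband anchor spikes plus a reference spike that pins the per-image
#'   maximum. The class is carried by a low-amplitude continuous tone
#'   (1.4 / 2 / 2.9 Hz) whose rendered intensity stays well below the
#'   mid-gray threshold: visible to the scalogram branch as a bright
#'   fixed-frequency band, erased entirely by binarization.
#' * `"binary_only"`: classes differ in beat-timing geometry (spike-train
#'   rate 50 / 90 / 150 bpm, with RR jitter for ARR) — the support pattern
#'   that survives binarization crisply — while per-beat gains, per-beat
#'   widths and a dense sub-threshold broadband noise floor randomize the
#'   continuous magnitudes.
#'
#' Note an asymmetry between the two directions: the binary image is a
#' deterministic threshold of the rendered scalogram, so its information is
#' always a subset of the continuous branch's. The scalogram-only probe can
#' therefore be made strictly modality-pure, whereas the binary-only probe
#' can only make the continuous view *noisier*, not less informative; see
#' the methods vignette for the consequences.
#'
#' @param which_modality `"scalogram_only"` or `"binary_only"`.
#' @param n_per_class Records per class (>= 10).
#' @param seed Integer seed.
#' @param fs,length As in [synth_spec()].
#' @return List of [ecg_record()]s.
#' @export
generate_modality_probe <- function(which_modality, n_per_class, seed,
                                    fs = 128, length = 2000) {
  assert_that(is.character(which_modality) && length(which_modality) == 1 &&
                which_modality %in% c("scalogram_only", "binary_only"),
              "which_modality must be 'scalogram_only' or 'binary_only'")
  assert_that(n_per_class >= 10, "n_per_class must be >= 10")
  len <- as.integer(length)
  dur <- len / fs
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (cls in ECG_CLASSES) {
      for (i in seq_len(n_per_class)) {
        id <- sprintf("%s_%03d", cls, i)
        tt <- seq(0, dur - 1 / fs, by = 1 / fs)
        if (which_modality == "scalogram_only") {
          # Class-free support: a reference spike pins the per-image
          # maximum, so the mid-gray threshold sits at half its magnitude;
          # the jittered anchor spikes stay safely above it and the class
          # tone (plus spike tails and noise) safely below.
          n_spk <- 10
          times <- (seq_len(n_spk) - 0.5) * dur / n_spk + runif(n_spk, -0.2, 0.2)
          y <- spike_train(times, runif(n_spk, 1.4, 1.8), 0.012, fs, len)
          y <- y + spike_train(runif(1, 0.3, dur - 0.3), 2.3, 0.012, fs, len)
          # tone frequencies sit well below the spikes' energy band, so the
          # tone row never superposes with near-threshold spike tails
          f_tone <- switch(cls, ARR = 1.4, CHF = 2, NSR = 2.9)
          y <- y + 0.06 * sin(2 * pi * f_tone * tt + runif(1, 0, 2 * pi))
          rec <- ecg_record(id, y + rnorm(len, 0, 0.01), fs, cls)
        } else {
          # Class-specific timing geometry: spike-train rate (and, for ARR,
          # irregularity) codes the class, so the stripe pattern survives
          # binarization; magnitudes are then randomized per record and
          # sub-threshold distractor stripes contaminate the continuous
          # rendering.
          bpm <- switch(cls, NSR = 50, ARR = 90, CHF = 150)
          cv <- if (cls == "ARR") 0.25 else 0.03
          mean_rr <- 60 / bpm
          n_beats <- ceiling(dur / mean_rr) + 4
          rr <- mean_rr * pmax(0.4, rnorm(n_beats, 1, cv))
          times <- cumsum(c(runif(1, 0, mean_rr), rr))
          times <- times[times < dur - 0.05 & times > 0.05]
          amps <- runif(length(times), 1.4, 1.8)        # iid beat gains
          widths <- runif(length(times), 0.02, 0.035)   # iid beat widths
          y <- rep(0, len)
          t_ax <- (seq_len(len) - 1) / fs
          for (b in seq_along(times)) {
            y <- y + amps[b] * exp(-((t_ax - times[b])^2) / (2 * widths[b]^2))
          }
          # reference spike pinning the maximum (see scalogram probe note)
          y <- y + spike_train(runif(1, 0.3, dur - 0.3), 2.3, 0.03, fs, len)
          # dense broadband noise floor at a random per-record level: its
          # time-frequency magnitude fills every pooling region of the
          # continuous rendering just below the threshold, so max-pooled
          # scalogram features saturate on this class-free floor, while
          # binarization clips it to black and keeps only the beat stripes
          y <- y + rnorm(len, 0, runif(1, 0.055, 0.085))
          rec <- ecg_record(id, y, fs, cls)
        }
        out[[id]] <- rec
      }
    }
    unname(out)
  })
}

# n aperiodic event times in (0.05, dur-0.05) with a minimum spacing.
spaced_times <- function(n, dur, min_gap) {
  times <- numeric(0)
  for (tries in 1:500) {
    cand <- runif(1, 0.05, dur - 0.05)
    if (all(abs(cand - times) >= min_gap)) times <- c(times, cand)
    if (length(times) == n) break
  }
  sort(times)
}

# Narrow Gaussian spikes at the given times with per-spike gains.
spike_train <- function(times, amps, width_s, fs, len) {
  t_ax <- (seq_len(len) - 1) / fs
  y <- rep(0, len)
  for (b in seq_along(times)) {
    y <- y + amps[b] * exp(-((t_ax - times[b])^2) / (2 * width_s^2))
  }
  y
}

# Magnitude scrambler for the binary-only probe: a dense multi-tone "carpet"
# whose overall level is drawn per record. The carpet floor shifts the whole
# continuous rendering (background level and colormap hues vary record to
# record, uncorrelated with class) yet stays below the mid-gray threshold,
# so the binarized support pattern is untouched.
randomize_magnitudes <- function(y, fs, dur) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  # carpet confined to 1.5-8 Hz: the beats' energy lives above ~19 Hz, so
  # the clutter never interferes destructively with stripe pixels near the
  # threshold, while it still repaints the low-frequency half of the
  # continuous rendering with record-specific bands
  level <- runif(1, 0.02, 0.05)
  for (j in 1:15) {
    y <- y + level * runif(1, 0.5, 1) *
      sin(2 * pi * runif(1, 1.5, 4) * tt + runif(1, 0, 2 * pi))
  }
  y + rnorm(length(y), 0, 0.01)
}
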