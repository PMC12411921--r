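test_that("generator respects class counts and is seed-deterministic", {
  spec <- synth_spec(c(ARR = 5, CHF = 3, NSR = 4), seed = 7, length = 1500)
  recs <- generate_dataset(spec)
  expect_equal(length(recs), 12)
  labs <- vapply(recs, `[[`, "", "label")
  expect_equal(as.integer(table(factor(labs, levels = ecg_classes()))),
               c(5L, 3L, 4L))
  recs2 <- generate_dataset(spec)
  expect_identical(recs, recs2)
  # a different seed changes the data
  recs3 <- generate_dataset(synth_spec(c(ARR = 5, CHF = 3, NSR = 4),
                                       seed = 8, length = 1500))
  expect_false(identical(recs[[1]]$samples, recs3[[1]]$samples))
})

test_that("noiseless jitter-free recipe gives an exactly periodic beat train", {
  params <- list(
    NSR = list(mean_rate_bpm = 75, rate_jitter_cv = 0, beat_template = "normal",
               amplitude_envelope = "flat", noise_sd = 0, ectopic_prob = 0),
    ARR = list(mean_rate_bpm = 75, rate_jitter_cv = 0, beat_template = "normal",
               amplitude_envelope = "flat", noise_sd = 0, ectopic_prob = 0),
    CHF = list(mean_rate_bpm = 75, rate_jitter_cv = 0, beat_template = "normal",
               amplitude_envelope = "flat", noise_sd = 0, ectopic_prob = 0))
  recs <- generate_dataset(synth_spec(c(ARR = 1, CHF = 1, NSR = 1), seed = 1,
                                      length = 4096, class_params = params))
  x <- recs[[3]]$samples
  lag_rr <- round(60 / 75 * 128)  # programmed RR interval in samples
  ac <- stats::acf(x, lag.max = 2 * lag_rr + 10, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[(lag_rr - 15):(lag_rr + 15)]) + lag_rr - 16, lag_rr,
               tolerance = 1)
})

test_that("generated RR intervals match the class mean rate", {
  # NSR recipe, long record: detected R-peak spacing ~ 60/75 s within 3 SE
  params <- default_class_params <- list(
    NSR = list(mean_rate_bpm = 75, rate_jitter_cv = 0.05, beat_template = "normal",
               amplitude_envelope = "flat", noise_sd = 0, ectopic_prob = 0),
    ARR = list(mean_rate_bpm = 75, rate_jitter_cv = 0.05, beat_template = "normal",
               amplitude_envelope = "flat", noise_sd = 0, ectopic_prob = 0),
    CHF = list(mean_rate_bpm = 75, rate_jitter_cv = 0.05, beat_template = "normal",
               amplitude_envelope = "flat", noise_sd = 0, ectopic_prob = 0))
  recs <- generate_dataset(synth_spec(c(ARR = 1, CHF = 1, NSR = 1), seed = 3,
                                      length = 100 * 103, class_params = params))
  x <- recs[[3]]$samples
  # R peaks: local maxima above half the max amplitude
  is_peak <- x > 0.5 * max(x) &
    x == vapply(seq_along(x), function(i) max(x[max(1, i - 20):min(length(x), i + 20)]), 0)
  rr <- diff(which(is_peak)) / 128
  se <- sd(rr) / sqrt(length(rr))
  expect_lt(abs(mean(rr) - 60 / 75), 3 * se + 1e-3)
})

test_that("spec validation rejects degenerate inputs", {
  expect_error(synth_spec(c(ARR = 0, CHF = 1, NSR = 1)), "> 0")
  expect_error(synth_spec(length = 10), "too short")
  expect_error(generate_modality_probe("both", 10, 1), "which_modality")
  expect_error(generate_modality_probe("scalogram_only", 5, 1), ">= 10")
})

test_that("modality probes are seed-deterministic and balanced", {
  p1 <- generate_modality_probe("binary_only", 10, seed = 5, length = 1200)
  p2 <- generate_modality_probe("binary_only", 10, seed = 5, length = 1200)
  expect_identical(p1, p2)
  expect_equal(length(p1), 30)
  expect_equal(unname(table(vapply(p1, `[[`, "", "label"))[ecg_classes()]),
               rep(10L, 3), ignore_attr = TRUE)
})

test_that("the scalogram-only probe is modality-pure: the binary branch
           alone classifies near chance", {
  sw <- probe_sweep("scalogram_only")
  acc_binary_branch <- sw$accuracy[sw$alpha == 0]
  expect_lte(acc_binary_branch, 1 / 3 + 0.10)
})
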