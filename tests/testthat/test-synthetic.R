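test_that("constant-rate degenerate config places beats exactly 1 s apart", {
  cfg <- synth_config(duration_s = 60, mean_rr_ms = 1000, rsa_amp_ms = 0,
                      breath_jitter_sd_hz = 0, noise_sd_ms = 0)
  rr <- generate_rr_series(cfg)
  expect_length(rr$beat_times, 61L)
  expect_equal(rr$rr_ms, rep(1000, 60))
})

test_that("beat count is conserved when all modulations are zero", {
  for (mu in c(700, 850, 1100)) {
    cfg <- synth_config(duration_s = 120, mean_rr_ms = mu, rsa_amp_ms = 0)
    n <- length(generate_rr_series(cfg)$beat_times)
    expect_lte(abs(n - (120 * 1000 / mu + 1)), 1)
  }
})

test_that("identical seeds reproduce series exactly; different seeds do not", {
  cfg <- guided_config(seed = 7, jitter = 0.01, noise = 8)
  a <- generate_rr_series(cfg)
  b <- generate_rr_series(cfg)
  expect_identical(a, b)
  cfg2 <- guided_config(seed = 8, jitter = 0.01, noise = 8)
  expect_false(identical(generate_rr_series(cfg2)$beat_times, a$beat_times))
  ra <- generate_resp_signal(cfg, fs = 1)
  expect_identical(ra, generate_resp_signal(cfg, fs = 1))
})

test_that("noiseless guided series puts its dominant frequency at 0.1 Hz", {
  cfg <- guided_config(seed = 1, jitter = 0, noise = 0)
  out <- guided_pipeline(generate_rr_series(cfg))
  pk <- main_peak(out$psd, c(0.04, 0.4))
  expect_equal(pk$location, 0.100)
  # independent oracle: FFT argmax of the analytic RR(t) sampled densely
  fs_o <- 4
  tt <- seq(0, 300, by = 1 / fs_o)
  x <- 60 * sin(2 * pi * 0.1 * tt + pi / 2)
  sp <- Mod(fft(x - mean(x)))^2
  half <- floor(length(x) / 2)
  f_oracle <- (which.max(sp[2:half])) * fs_o / length(x)
  expect_lt(abs(f_oracle - 0.1), 0.005)
  expect_lt(abs(pk$location - f_oracle), 0.005)
})

test_that("with no jitter or noise, variance concentrates at the modulation frequencies", {
  cfg <- synth_config(duration_s = 300, mean_rr_ms = 900, rsa_amp_ms = 50,
                      breath_freq_hz = 0.25, mayer_amp_ms = 30,
                      mayer_freq_hz = 0.1, seed = 3)
  rr <- generate_rr_series(cfg)
  # dense-sampling FFT oracle on the resampled series
  tach <- resample_tachogram(rr, 4)
  x <- tach$values - mean(tach$values)
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (0:(n - 1)) * 4 / n
  half <- f <= 2
  inband <- half & ((abs(f - 0.25) <= 0.01) | (abs(f - 0.1) <= 0.01))
  expect_gte(sum(p[inband]) / sum(p[half & f > 0]), 0.95)
})

test_that("respiration waveform has pure 10-s cycles when clean", {
  cfg <- synth_config(duration_s = 300, breath_freq_hz = 0.1,
                      breath_jitter_sd_hz = 0, resp_noise_sd = 0)
  resp <- generate_resp_signal(cfg, fs = 1)
  expect_length(resp$samples, 300L)
  cyc <- detect_resp_cycles(resp)
  expect_equal(cyc$n, 29L)
  expect_equal(cyc$durations, rep(10, 29), tolerance = 1e-8)
})

test_that("excess respiration noise triggers the unusable-series signal", {
  cfg <- synth_config(duration_s = 300, breath_freq_hz = 0.1,
                      resp_noise_sd = 3, seed = 5)
  resp <- generate_resp_signal(cfg, fs = 1)
  expect_error(detect_resp_cycles(resp), class = "hrvc_excluded_series")
})

test_that("ectopic injection follows the 0.6x / 1.4x rule and preserves time", {
  base <- analytic_rr_series(function(t) 1000, 300)
  none <- inject_ectopics(base, 0, seed = 1)
  expect_identical(none$rr$rr_ms, base$rr_ms)
  expect_length(none$indices, 0L)

  inj <- inject_ectopics(base, 2, seed = 42)
  k <- inj$onsets
  expect_true(length(k) > 0)
  expect_equal(inj$rr$rr_ms[k], rep(600, length(k)))
  expect_equal(inj$rr$rr_ms[k + 1L], rep(1400, length(k)))
  expect_equal(max(inj$rr$beat_times), max(base$beat_times), tolerance = 1e-9)
  # Poisson-consistent count at 2/min over 5 min: well within 10 +/- 4 sd
  counts <- vapply(1:20, function(s) length(inject_ectopics(base, 2, s)$onsets),
                   numeric(1))
  expect_gt(mean(counts), 10 - 3 * sqrt(10 / 20))
  expect_lt(mean(counts), 10 + 3 * sqrt(10 / 20))
  expect_error(inject_ectopics(base, 500, seed = 1), class = "hrvc_config_error")
})

test_that("configuration errors name the offending field", {
  expect_error(synth_config(duration_s = -1), "duration_s",
               class = "hrvc_config_error")
  expect_error(synth_config(breath_freq_hz = 0.6), "breath_freq_hz",
               class = "hrvc_config_error")
  expect_error(synth_config(mean_rr_ms = 100, rsa_amp_ms = 95, noise_sd_ms = 2),
               "mean_rr_ms",
               class = "hrvc_config_error")
  expect_error(generate_resp_signal(guided_config(1), fs = 0),
               class = "hrvc_config_error")
})

test_that("cohorts have one series per participant and phase, reproducibly", {
  cc <- cohort_config(n_visual = 1, n_haptic = 1, n_visuo_haptic = 1, seed = 2)
  coh <- generate_cohort(cc)
  expect_length(coh$participants, 3L)
  expect_equal(nrow(coh$manifest), 6L)
  expect_setequal(unique(coh$manifest$phase), c("video", "guided"))
  for (p in coh$participants) {
    expect_s3_class(p$guided$rr, "rr_series")
    expect_s3_class(p$video$resp, "resp_signal")
  }
  coh2 <- generate_cohort(cc)
  expect_identical(coh$participants[[1]]$guided$rr,
                   coh2$participants[[1]]$guided$rr)
})
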