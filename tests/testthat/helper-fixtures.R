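# Shared fixtures, all built in code.

# Beat series placed iteratively from an analytic RR(t) (ms), independent of
# the package generator: the oracle substrate for resampling/cycle tests.
analytic_rr_series <- function(rr_fun, duration_s) {
  t <- 0
  beats <- numeric(0)
  while (t <= duration_s + 1e-9) {
    beats <- c(beats, t)
    t <- t + rr_fun(t) / 1000
  }
  rr_series(beats)
}

# RR(t) phase-locked to the pacing device: heart rate rises over [0, 5) and
# falls over [5, 10) within each 10-s cycle.
device_locked_rr <- function(t, mean_ms = 850, amp_ms = 60) {
  mean_ms + amp_ms * cos(2 * pi * 0.1 * t)
}

# Guided-phase pipeline: artifact correction, 4 Hz resampling, detrending.
guided_pipeline <- function(rr, lambda = 300) {
  rr2 <- suppressWarnings(correct_artifacts(rr, detect_artifacts(rr)))
  det <- smoothness_priors_detrend(resample_tachogram(rr2, 4), lambda)
  list(rr = rr2, tach = det, psd = compute_psd(det))
}

guided_config <- function(seed, jitter = 0.005, noise = 5, duration = 300,
                          ...) {
  synth_config(duration_s = duration, mean_rr_ms = 850, rsa_amp_ms = 60,
               breath_freq_hz = 0.1, breath_jitter_sd_hz = jitter,
               noise_sd_ms = noise, seed = seed, ...)
}

# A psd_result with prescribed triangular bumps (for closed-form P0.1 tests):
# heights at given centres, linear flanks of half-width w, zero elsewhere.
bump_psd <- function(centres, heights, w = 0.01, df = 0.001, fmax = 0.5) {
  f <- seq(0, fmax, by = df)
  d <- rep(0, length(f))
  for (i in seq_along(centres))
    d <- pmax(d, heights[i] * pmax(0, 1 - abs(f - centres[i]) / w))
  psd_result(f, d, window_name = "hann", segment_length_s = 300, pad_factor = 4)
}
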