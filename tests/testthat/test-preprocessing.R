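test_that("artifact detector flags ectopic pairs and nothing on clean series", {
  flat <- analytic_rr_series(function(t) 1000, 120)
  expect_length(detect_artifacts(flat), 0L)

  inj <- inject_ectopics(flat, 1, seed = 3)
  flagged <- detect_artifacts(inj$rr)
  expect_setequal(flagged, inj$indices)

  expect_error(detect_artifacts(rr_series(seq(0, 5, by = 1))),
               class = "hrvc_config_error")
})

test_that("artifact detector meets sensitivity/false-positive targets on generator truth", {
  hits <- 0; truths <- 0; fps <- 0; negs <- 0
  for (s in 1:4) {
    rr <- generate_rr_series(guided_config(seed = s, jitter = 0.005, noise = 10))
    inj <- inject_ectopics(rr, 2, seed = 100 + s)
    flagged <- detect_artifacts(inj$rr)
    truths <- truths + length(inj$indices)
    hits <- hits + length(intersect(flagged, inj$indices))
    fps <- fps + length(setdiff(flagged, inj$indices))
    negs <- negs + length(inj$rr$rr_ms) - length(inj$indices)
  }
  expect_gte(hits / truths, 0.9)
  expect_lte(fps / negs, 0.02)
})

test_that("correction interpolates flagged intervals and preserves total time", {
  flat <- analytic_rr_series(function(t) 1000, 60)
  inj <- inject_ectopics(flat, 2, seed = 9)
  fixed <- suppressWarnings(correct_artifacts(inj$rr, inj$indices))
  expect_equal(fixed$rr_ms, flat$rr_ms, tolerance = 1e-9)
  expect_equal(fixed$corrected_fraction, length(inj$indices) / length(flat$rr_ms))
  expect_lt(abs(max(fixed$beat_times) - max(inj$rr$beat_times)) /
              max(inj$rr$beat_times), 0.02)

  # no-op on empty index list
  expect_identical(correct_artifacts(flat, integer(0)), flat)

  # linear ramp: replacement is the midpoint of its neighbours
  ramp <- rr_series(cumsum(c(0, seq(800, 1200, by = 25))) / 1000)
  mid <- 8L
  out <- suppressWarnings(correct_artifacts(ramp, mid))
  expect_equal(out$rr_ms[mid], (ramp$rr_ms[mid - 1] + ramp$rr_ms[mid + 1]) / 2)

  expect_error(correct_artifacts(flat, seq_along(flat$rr_ms)),
               class = "hrvc_corrupt_series")
  expect_warning(correct_artifacts(flat, 1:5), class = "hrvc_corruption_warning")
})

test_that("correction is a no-op on clean generator output (round trip)", {
  rr <- generate_rr_series(guided_config(seed = 11, jitter = 0.005, noise = 5))
  fixed <- correct_artifacts(rr, detect_artifacts(rr))
  expect_equal(fixed$rr_ms, rr$rr_ms, tolerance = 1e-12)
})

test_that("tachogram resampling: grid, constants and spline accuracy", {
  flat <- analytic_rr_series(function(t) 1000, 60)
  tach <- resample_tachogram(flat, 4)
  expect_equal(tach$values, rep(1000, length(tach$values)))
  expect_equal(diff(tach_times <- tach$start_time +
                      (seq_along(tach$values) - 1) / 4),
               rep(0.25, length(tach$values) - 1))
  span <- flat$beat_times[length(flat$beat_times) - 1] - flat$beat_times[1]
  expect_length(tach$values, floor(span * 4) + 1)

  rr_fun <- function(t) 1000 + 50 * sin(2 * pi * 0.05 * t)
  rr <- analytic_rr_series(rr_fun, 120)
  tach <- resample_tachogram(rr, 4)
  grid <- tach$start_time + (seq_along(tach$values) - 1) / 4
  expect_lt(max(abs(tach$values - rr_fun(grid))), 1)

  expect_error(resample_tachogram(rr_series(c(0, 1, 2)), 4),
               class = "hrvc_config_error")
})

test_that("respiratory cycle detection handles sines, jitter and flat signals", {
  # jittered sine: mean duration near the 10-s target
  cfg <- synth_config(duration_s = 300, breath_freq_hz = 0.1,
                      breath_jitter_sd_hz = 0.005, resp_noise_sd = 0.05,
                      seed = 21)
  cyc <- detect_resp_cycles(generate_resp_signal(cfg, fs = 1))
  expect_lt(abs(mean(cyc$durations) - 10), 0.5)

  expect_error(detect_resp_cycles(resp_signal(rep(1, 300), fs = 1)),
               class = "hrvc_excluded_series")
})

test_that("HRV cycle detection recovers 10-s cycles and cycle-count scaling", {
  tt <- seq(0, 300, by = 0.25)
  tach <- tachogram(50 * sin(2 * pi * 0.1 * tt), fs = 4, detrended = TRUE)
  cyc <- detect_hrv_cycles(tach)
  expect_equal(cyc$n, 29L)
  expect_equal(cyc$durations, rep(10, 29))

  # pure f-Hz oscillation of duration T: floor(T*f) +/- 1 detected cycles
  for (f in c(0.08, 0.1, 0.12)) {
    x <- sin(2 * pi * f * tt)
    n <- detect_hrv_cycles(tachogram(x, 4, detrended = TRUE))$n
    expect_lte(abs(n - floor(300 * f)), 1)
  }

  # 1% amplitude white noise barely perturbs durations
  set.seed(4)
  noisy <- tachogram(50 * sin(2 * pi * 0.1 * tt) + rnorm(length(tt), 0, 0.5),
                     fs = 4, detrended = TRUE)
  d <- detect_hrv_cycles(noisy)$durations
  expect_true(all(abs(d - 10) < 0.5))

  # guided 5-min synthetic with small jitter: ~30 cycles at 0.1 Hz
  out <- guided_pipeline(generate_rr_series(guided_config(seed = 2)))
  n_peaks <- detect_hrv_cycles(out$tach)$n + 1L
  expect_lte(abs(n_peaks - 30), 1)

  expect_error(detect_hrv_cycles(tachogram(rep(1, 100), 4, detrended = TRUE)),
               class = "hrvc_no_peak")
})
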