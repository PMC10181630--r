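# Beat-series cleaning, tachogram resampling and oscillation-cycle extraction.

#' Detect artifact/ectopic intervals in an RR series
#'
#' Flags interval `k` when its relative deviation from the median of its 5
#' nearest neighbouring intervals (excluding `k` itself; ties toward earlier
#' indices) exceeds `rel_threshold`. An extrasystole (0.6x) and its
#' compensatory pause (1.4x) both deviate by 40% and are caught at the
#' default 20% threshold, while respiratory sinus arrhythmia at physiological
#' amplitude stays well below it.
#'
#' @param rr An [rr_series()] with at least 7 intervals.
#' @param rel_threshold Relative deviation threshold (default 0.2).
#' @return Integer vector of flagged interval indices.
#' @export
detect_artifacts <- function(rr, rel_threshold = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  check_scalar(rel_threshold, "rel_threshold", min = 0, strict_min = TRUE)
  x <- rr$rr_ms
  n <- length(x)
  if (n < 7L)
    hrvc_error("RR series too short for artifact detection (need >= 7 intervals)",
               "hrvc_config_error")
  med <- numeric(n)
  # interior: 5 nearest neighbours are k-3, k-2, k-1, k+1, k+2
  interior <- 4:(n - 2L)
  if (length(interior) > 0) {
    nb <- cbind(x[interior - 3L], x[interior - 2L], x[interior - 1L],
                x[interior + 1L], x[interior + 2L])
    med[interior] <- apply(nb, 1L, stats::median)
  }
  for (k in setdiff(seq_len(n), interior)) {
    others <- setdiff(seq_len(n), k)
    nb_idx <- others[order(abs(others - k), others)][1:5]
    med[k] <- stats::median(x[nb_idx])
  }
  which(abs(x - med) / med > rel_threshold)
}

#' Replace flagged intervals by interpolation
#'
#' Flagged intervals are replaced by linear interpolation between the nearest
#' non-flagged intervals; beat times are rebuilt cumulatively from the first
#' beat. A warning is emitted when more than 2% of intervals needed
#' correction (recordings should be cleaner than that).
#'
#' @param rr An [rr_series()].
#' @param indices Interval indices to correct (e.g. from [detect_artifacts()]).
#' @return A corrected [rr_series()] with updated `corrected_fraction`.
#' @export
correct_artifacts <- function(rr, indices) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr_ms
  n <- length(x)
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0) return(rr)
  if (any(indices < 1L | indices > n))
    hrvc_error("artifact indices out of range", "hrvc_config_error")
  good <- setdiff(seq_len(n), indices)
  if (length(good) == 0)
    hrvc_error("all intervals flagged: series unrecoverable", "hrvc_corrupt_series")
  x[indices] <- stats::approx(good, x[good], xout = indices, rule = 2)$y
  frac <- rr$corrected_fraction + length(indices) / n
  if (frac > 0.02)
    warning(warningCondition(
      sprintf("%.1f%% of intervals corrected (expected < 2%% in clean recordings)",
              100 * frac),
      class = c("hrvc_corruption_warning", "warning")))
  beats <- rr$beat_times[1] + c(0, cumsum(x)) / 1000
  rr_series(beats, corrected_fraction = frac)
}

#' Resample an RR series to a uniform tachogram
#'
#' Cubic-spline interpolation of interval duration against interval start
#' time, evaluated on a uniform grid (4 Hz by convention). The grid is
#' clamped to the data span; no extrapolation is performed.
#'
#' @param rr An [rr_series()] with at least 4 beats.
#' @param fs Target sampling rate in Hz.
#' @return A [tachogram()].
#' @export
resample_tachogram <- function(rr, fs = 4) {
  stopifnot(inherits(rr, "rr_series"))
  check_scalar(fs, "fs", min = 0, strict_min = TRUE)
  if (length(rr$beat_times) < 4L)
    hrvc_error("need at least 4 beats for cubic-spline resampling",
               "hrvc_config_error")
  x <- rr$beat_times[-length(rr$beat_times)]
  y <- rr$rr_ms
  sf <- stats::splinefun(x, y, method = "fmm")
  t0 <- x[1]
  m <- floor((x[length(x)] - t0) * fs)
  grid <- t0 + (0:m) / fs
  tachogram(sf(grid), fs = fs, start_time = t0, detrended = FALSE)
}

# Local maxima of a numeric vector with plateau handling, topographic
# prominence and a minimum-separation rule (taller peaks win).
find_peaks <- function(x, min_sep = 1L, min_prom = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # run-length encode to handle plateaus: a plateau is a peak when the
  # preceding run is lower and the following run is lower
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  m <- length(v)
  cand <- integer(0)
  for (i in seq_len(m)) {
    if (i == 1L || i == m) next
    if (v[i] > v[i - 1L] && v[i] > v[i + 1L])
      cand <- c(cand, starts[i] + (r$lengths[i] - 1L) %/% 2L)
  }
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(k) {
    pk <- x[k]
    j <- k
    left_min <- pk
    while (j > 1L) {
      j <- j - 1L
      if (x[j] > pk) break
      if (x[j] < left_min) left_min <- x[j]
    }
    j <- k
    right_min <- pk
    while (j < n) {
      j <- j + 1L
      if (x[j] > pk) break
      if (x[j] < right_min) right_min <- x[j]
    }
    pk - max(left_min, right_min)
  }, numeric(1))
  cand <- cand[prom >= min_prom]
  if (length(cand) <= 1L) return(cand)
  # greedy minimum-separation: keep taller peaks first
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (k in ord)
    if (all(abs(k - kept) >= min_sep)) kept <- c(kept, k)
  sort(kept)
}

# Sub-sample refinement of peak positions by a parabola through the peak bin
# and its neighbours; returns fractional indices (1-based). Compensates the
# coarse (e.g. 1 Hz) sampling of respiration relative to 10-s cycles.
refine_peak_pos <- function(x, pk) {
  vapply(pk, function(k) {
    if (k <= 1L || k >= length(x)) return(as.numeric(k))
    den <- x[k - 1L] - 2 * x[k] + x[k + 1L]
    delta <- if (den != 0) clamp(0.5 * (x[k - 1L] - x[k + 1L]) / den, -0.5, 0.5) else 0
    k + delta
  }, numeric(1))
}

#' Extract respiratory cycles from a respiration waveform
#'
#' Detects end-of-inspiration peaks (local maxima with minimum separation
#' `min_sep_s` and prominence at least `prom_frac` of the signal
#' interquartile range) on a 1 Hz grid, and returns the successive
#' peak-to-peak delays. The series is rejected as unusable -- a classed
#' `hrvc_excluded_series` error -- when the detected cycle count deviates by
#' more than `count_tol` from the count expected at the 0.1 Hz target, the
#' guard used to exclude low signal-to-noise chest-belt recordings.
#'
#' @param resp A [resp_signal()]; resampled internally to 1 Hz if needed.
#' @param min_sep_s Minimum peak separation (s).
#' @param prom_frac Prominence threshold as a fraction of the IQR.
#' @param expected_freq_hz Breathing frequency used by the count guard (Hz).
#' @param count_tol Allowed relative deviation of cycle count (default 0.3).
#' @return A [cycle_series()] with `source = "respiration"`.
#' @export
detect_resp_cycles <- function(resp, min_sep_s = 3, prom_frac = 0.25,
                               expected_freq_hz = 0.1, count_tol = 0.3) {
  stopifnot(inherits(resp, "resp_signal"))
  x <- resp$samples
  fs <- resp$fs
  if (fs != 1) {
    tt <- resp$start_time + (seq_along(x) - 1) / fs
    grid <- seq(tt[1], tt[length(tt)], by = 1)
    x <- stats::approx(tt, x, xout = grid)$y
    fs <- 1
  }
  dur <- length(x) / fs
  iqr <- stats::IQR(x)
  pk <- if (iqr > 0)
    find_peaks(x, min_sep = ceiling(min_sep_s * fs), min_prom = prom_frac * iqr)
  else integer(0)
  expected <- dur * expected_freq_hz
  n_cycles <- max(0L, length(pk) - 1L)
  if (length(pk) < 2L || abs(n_cycles - expected) / expected > count_tol)
    hrvc_error(sprintf(
      "respiration series unusable: %d cycles detected where ~%.0f expected (insufficient signal-to-noise)",
      n_cycles, expected), "hrvc_excluded_series")
  times <- resp$start_time + (refine_peak_pos(x, pk) - 1) / fs
  cycle_series(diff(times), source = "respiration")
}

#' Extract HRV oscillation cycles from a tachogram
#'
#' Peak-to-peak delays of the tachogram oscillation: local maxima with
#' minimum separation `min_sep_s` (safely below the 10-s resonance period)
#' and prominence at least `prom_frac` of the tachogram IQR.
#'
#' @param tach A [tachogram()], detrended or slowly trending.
#' @param min_sep_s Minimum peak separation (s).
#' @param prom_frac Prominence threshold as a fraction of the IQR.
#' @return A [cycle_series()] with `source = "hrv"`.
#' @export
detect_hrv_cycles <- function(tach, min_sep_s = 5, prom_frac = 0.25) {
  stopifnot(inherits(tach, "tachogram"))
  iqr <- stats::IQR(tach$values)
  pk <- if (iqr > 0)
    find_peaks(tach$values, min_sep = ceiling(min_sep_s * tach$fs),
               min_prom = prom_frac * iqr)
  else integer(0)
  if (length(pk) < 2L)
    hrvc_error("fewer than 2 HRV oscillation peaks found", "hrvc_no_peak")
  times <- tach$start_time + (refine_peak_pos(tach$values, pk) - 1) / tach$fs
  cycle_series(diff(times), source = "hrv")
}
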