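#' Beat-event RR-interval series
#'
#' Container for a heartbeat event series: beat times in seconds from the
#' start of the recording and the RR interval durations in milliseconds.
#' Intervals are attributed to the interval's starting beat, so `rr_ms` has
#' one element fewer than `beat_times`.
#'
#' @param beat_times Numeric vector of beat times (s), strictly increasing.
#' @param corrected_fraction Fraction of intervals that were replaced by
#'   interpolation during artifact correction (0 for raw series).
#' @return An object of class `rr_series`: a list with elements `beat_times`,
#'   `rr_ms` and `corrected_fraction`.
#' @examples
#' rr <- rr_series(seq(0, 10, by = 0.8))
#' rr$rr_ms
#' @export
rr_series <- function(beat_times, corrected_fraction = 0) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L)
    hrvc_error("an RR series needs at least 2 beats", "hrvc_config_error")
  d <- diff(beat_times)
  if (any(d <= 0))
    hrvc_error("beat times must be strictly increasing", "hrvc_config_error")
  structure(list(beat_times = beat_times,
                 rr_ms = 1000 * d,
                 corrected_fraction = corrected_fraction),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s, mean RR %.1f ms",
              length(x$beat_times), diff(range(x$beat_times)),
              mean(x$rr_ms)))
  if (x$corrected_fraction > 0)
    cat(sprintf(" (%.1f%% intervals corrected)", 100 * x$corrected_fraction))
  cat("\n")
  invisible(x)
}

#' Uniformly sampled tachogram
#'
#' RR interval duration as a function of time on a uniform grid, the input
#' to spectral analysis.
#'
#' @param values RR values (ms) on the uniform grid.
#' @param fs Sampling rate in Hz (4 Hz is the conventional choice).
#' @param start_time Time (s) of the first sample.
#' @param detrended Logical; `TRUE` after smoothness-priors detrending.
#' @return An object of class `tachogram`.
#' @export
tachogram <- function(values, fs, start_time = 0, detrended = FALSE) {
  check_scalar(fs, "fs", min = 0, strict_min = TRUE)
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    hrvc_error("tachogram values must be finite", "hrvc_config_error")
  structure(list(values = values, fs = fs, start_time = start_time,
                 detrended = detrended),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$values), x$fs, length(x$values) / x$fs,
              if (x$detrended) ", detrended" else ""))
  invisible(x)
}

# Sample times of a tachogram.
tach_times <- function(tach) {
  tach$start_time + (seq_along(tach$values) - 1) / tach$fs
}

#' Respiration waveform
#'
#' @param samples Amplitude samples (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param start_time Time (s) of the first sample.
#' @return An object of class `resp_signal`.
#' @export
resp_signal <- function(samples, fs, start_time = 0) {
  check_scalar(fs, "fs", min = 0, strict_min = TRUE)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    hrvc_error("respiration samples must be finite", "hrvc_config_error")
  structure(list(samples = samples, fs = fs, start_time = start_time),
            class = "resp_signal")
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("<resp_signal> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Oscillation cycle durations
#'
#' Durations of successive peak-to-peak oscillation cycles, either of the
#' heart-rate signal or of the respiration waveform. These are the quantities
#' compared to the 10-s resonance target by [rms_error()].
#'
#' @param durations Cycle durations in seconds.
#' @param source `"hrv"` or `"respiration"`.
#' @return An object of class `cycle_series`.
#' @export
cycle_series <- function(durations, source = c("hrv", "respiration")) {
  source <- match.arg(source)
  durations <- as.numeric(durations)
  if (length(durations) < 1L)
    hrvc_error("cycle series must contain at least one cycle", "hrvc_config_error")
  if (any(durations <= 0))
    hrvc_error("cycle durations must be positive", "hrvc_config_error")
  structure(list(durations = durations, n = length(durations), source = source),
            class = "cycle_series")
}

#' @export
print.cycle_series <- function(x, ...) {
  cat(sprintf("<cycle_series:%s> %d cycles, mean %.2f s (SD %.2f)\n",
              x$source, x$n, mean(x$durations), stats::sd(x$durations)))
  invisible(x)
}

# One-sided PSD container. Constructed by compute_psd(); kept internal-ish
# but documented because tests and advanced users may build one directly.

#' One-sided power spectral density
#'
#' @param freqs Frequencies (Hz), starting at 0, uniformly spaced.
#' @param density Power density (ms^2/Hz for tachograms).
#' @param window_name Taper used by the estimator.
#' @param segment_length_s Length of the analyzed record in seconds.
#' @param pad_factor Zero-padding factor of the transform.
#' @return An object of class `psd_result`.
#' @export
psd_result <- function(freqs, density, window_name, segment_length_s,
                       pad_factor) {
  freqs <- as.numeric(freqs); density <- as.numeric(density)
  if (length(freqs) != length(density) || length(freqs) < 2L)
    hrvc_error("freqs and density must have equal length >= 2", "hrvc_config_error")
  if (abs(freqs[1]) > 1e-12)
    hrvc_error("PSD frequencies must start at 0", "hrvc_config_error")
  df <- freqs[2] - freqs[1]
  if (any(abs(diff(freqs) - df) > 1e-9 * df))
    hrvc_error("PSD frequencies must be uniformly spaced", "hrvc_config_error")
  if (any(density < 0))
    hrvc_error("PSD density must be non-negative", "hrvc_config_error")
  structure(list(freqs = freqs, density = density, df = df,
                 window_name = window_name,
                 segment_length_s = segment_length_s,
                 pad_factor = pad_factor),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d bins, df = %.5g Hz, window = %s, record %.0f s\n",
              length(x$freqs), x$df, x$window_name, x$segment_length_s))
  invisible(x)
}
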