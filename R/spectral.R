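# PSD estimation and dominant-peak analytics.

#' Power spectral density of a uniformly sampled signal
#'
#' Single-segment periodogram of the full record with a cosine (Hann) taper
#' and density scaling (power per Hz), zero-padded to the next power of two
#' at least `pad_factor` times the record length so that peak interpolation
#' is stable. A single segment (rather than Welch averaging) preserves the
#' narrow resonance peak that segment averaging would broaden; density
#' scaling makes records of different durations comparable.
#'
#' @param x A [tachogram()], [resp_signal()], or numeric vector.
#' @param fs Sampling rate in Hz (ignored for classed inputs).
#' @param window `"hann"` (default) or `"boxcar"`.
#' @param pad_factor Minimum zero-padding factor (>= 1).
#' @return A [psd_result()].
#' @export
compute_psd <- function(x, fs = NULL, window = c("hann", "boxcar"),
                        pad_factor = 4) {
  window <- match.arg(window)
  if (inherits(x, "tachogram")) {
    if (!x$detrended)
      warning("computing the PSD of a tachogram that was not detrended")
    fs <- x$fs; x <- x$values
  } else if (inherits(x, "resp_signal")) {
    fs <- x$fs; x <- x$samples
  } else {
    if (is.null(fs))
      hrvc_error("fs must be given for a plain numeric signal", "hrvc_config_error")
  }
  check_scalar(fs, "fs", min = 0, strict_min = TRUE)
  check_scalar(pad_factor, "pad_factor", min = 1)
  n <- length(x)
  if (n < 64L)
    hrvc_error("signal too short for spectral analysis (need >= 64 samples)",
               "hrvc_config_error")
  w <- switch(window,
              hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
              boxcar = rep(1, n))
  xm <- (x - mean(x)) * w
  nfft <- 2^ceiling(log2(pad_factor * n))
  X <- stats::fft(c(xm, rep(0, nfft - n)))
  half <- nfft %/% 2L
  dens <- Mod(X[1:(half + 1L)])^2 / (fs * sum(w^2))
  dens[2:half] <- 2 * dens[2:half]  # one-sided; DC and Nyquist not doubled
  psd_result(freqs = (0:half) * fs / nfft, density = dens,
             window_name = window, segment_length_s = n / fs,
             pad_factor = pad_factor)
}

# indices of psd bins inside [lo, hi]
band_idx <- function(psd, band) {
  if (length(band) != 2L || band[1] < 0 || band[2] <= band[1] ||
      band[2] > psd$freqs[length(psd$freqs)] + 1e-12)
    hrvc_error("band must satisfy 0 <= lo < hi <= Nyquist", "hrvc_config_error")
  which(psd$freqs >= band[1] & psd$freqs <= band[2])
}

#' Dominant spectral peak in a band
#'
#' Finds the maximal density bin in the band, refines its location by
#' parabolic interpolation over the 3 bins around it (reported to 3
#' decimals), and measures the mid-peak-height width (MPHW): the width at
#' half the peak height, found by linear interpolation of the density on each
#' flank. The height is read at the raw maximal bin, not the interpolated
#' vertex, so heights are comparable across records sharing a frequency grid.
#'
#' @param psd A [psd_result()].
#' @param band Numeric `c(lo, hi)` in Hz; default 0.04-0.4, the HRV band.
#' @return An object of class `spectral_peak`: list with `location` (Hz),
#'   `height` (density units), `mphw` (Hz, `NA` if the half-height level is
#'   never crossed inside the spectrum).
#' @export
main_peak <- function(psd, band = c(0.04, 0.4)) {
  stopifnot(inherits(psd, "psd_result"))
  idx <- band_idx(psd, band)
  d <- psd$density
  k <- idx[which.max(d[idx])]
  # require a strict interior local maximum: monotone or flat density in the
  # band is reported as absence of a peak
  if (k <= 1L || k >= length(d) || d[k] <= d[k - 1L] || d[k] <= d[k + 1L])
    hrvc_error("no local maximum in the requested band", "hrvc_no_peak")
  denom <- d[k - 1L] - 2 * d[k] + d[k + 1L]
  delta <- if (denom != 0) 0.5 * (d[k - 1L] - d[k + 1L]) / denom else 0
  location <- round(psd$freqs[k] + delta * psd$df, 3)
  height <- d[k]
  half <- height / 2
  f_left <- f_right <- NA_real_
  j <- k
  while (j > 1L) {
    j <- j - 1L
    if (d[j] <= half) {
      f_left <- psd$freqs[j] + psd$df * (half - d[j]) / (d[j + 1L] - d[j])
      break
    }
  }
  j <- k
  while (j < length(d)) {
    j <- j + 1L
    if (d[j] <= half) {
      f_right <- psd$freqs[j] - psd$df * (half - d[j]) / (d[j - 1L] - d[j])
      break
    }
  }
  mphw <- f_right - f_left
  structure(list(location = location, height = height, mphw = mphw),
            class = "spectral_peak")
}

#' @export
print.spectral_peak <- function(x, ...) {
  cat(sprintf("<spectral_peak> location %.3f Hz, height %.4g, MPHW %.4g Hz\n",
              x$location, x$height, x$mphw))
  invisible(x)
}

#' Heights of all local density maxima in a band
#'
#' Strict local maxima of the density restricted to the band (bin `k` with
#' `density[k] > density[k-1]` and `> density[k+1]`); the band endpoints
#' cannot be peaks. This is the denominator ingredient of the P0.1 index:
#' the cumulative sum of peak heights over 0.04-0.4 Hz of the spontaneous
#' phase. No prominence filtering is applied by default.
#'
#' @param psd A [psd_result()].
#' @param band Numeric `c(lo, hi)` in Hz.
#' @param min_prominence Optional prominence threshold (density units).
#' @return Numeric vector of peak heights (possibly empty), with the peak
#'   frequencies attached as attribute `"freq"`.
#' @export
local_peak_heights <- function(psd, band = c(0.04, 0.4), min_prominence = 0) {
  stopifnot(inherits(psd, "psd_result"))
  idx <- band_idx(psd, band)
  if (length(idx) < 3L) return(numeric(0))
  d <- psd$density
  interior <- idx[-c(1L, length(idx))]
  is_pk <- d[interior] > d[interior - 1L] & d[interior] > d[interior + 1L]
  pk <- interior[is_pk]
  if (min_prominence > 0 && length(pk) > 0) {
    keep <- find_peaks(d, min_sep = 1L, min_prom = min_prominence)
    pk <- intersect(pk, keep)
  }
  structure(d[pk], freq = psd$freqs[pk])
}
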