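# The two bespoke coherence scores: RMSError against the 10-s resonance
# target and the P0.1 spectral-concentration index.

#' Root-mean-square error of cycle durations against the resonance target
#'
#' \deqn{RMSError = \sqrt{\frac{1}{N}\sum_{n=1}^{N}(x_n - 10)^2}}
#' with \eqn{x_n} the duration in seconds of the n-th oscillation cycle
#' (cardiac or respiratory) and 10 s the period of the 0.1 Hz pacing target.
#' Optionally trims leading/trailing cycles (transients at phase boundaries).
#'
#' @param cycles A [cycle_series()] or numeric vector of durations (s).
#' @param target_s Target cycle duration in seconds (default 10).
#' @param trim Integer `c(head, tail)`: cycles to drop at each end.
#' @return An object of class `rmse_result`: list with `rmse` (s), `target_s`,
#'   `n_cycles` (retained) and `trimmed`.
#' @examples
#' rms_error(c(9, 11, 9, 11))$rmse  # 1
#' @export
rms_error <- function(cycles, target_s = 10, trim = c(0L, 0L)) {
  x <- if (inherits(cycles, "cycle_series")) cycles$durations else as.numeric(cycles)
  check_scalar(target_s, "target_s", min = 0, strict_min = TRUE)
  trim <- rep_len(as.integer(trim), 2L)
  if (any(trim < 0)) config_error("trim", "must be non-negative counts")
  n <- length(x)
  if (sum(trim) >= n)
    hrvc_error("no cycles remain after trimming", "hrvc_config_error")
  keep <- x[seq.int(trim[1] + 1L, n - trim[2])]
  structure(list(rmse = sqrt(mean((keep - target_s)^2)),
                 target_s = target_s, n_cycles = length(keep), trimmed = trim),
            class = "rmse_result")
}

#' @export
print.rmse_result <- function(x, ...) {
  cat(sprintf("<rmse_result> %.3f s over %d cycles (target %g s)\n",
              x$rmse, x$n_cycles, x$target_s))
  invisible(x)
}

#' P0.1 spectral concentration index
#'
#' Ratio of the maximal PSD peak height during guided breathing to the
#' cumulative sum of the local peak heights in the 0.04-0.4 Hz band of the
#' spontaneous (video) phase:
#' \deqn{P_{0.1} = H_{max}^{guide} / \sum_{f=0.04}^{0.4} H^{video}.}
#' A value near 1 means the autonomic power that was spread across the HRV
#' band during spontaneous breathing has accumulated at the guided 0.1 Hz
#' frequency. Values above 1 are possible and are flagged, not clipped.
#'
#' Both PSDs must come from the same estimator settings (window and padding);
#' the guided-phase peak is the band-wide maximum, with its location reported
#' so proximity to 0.1 Hz can be checked separately.
#'
#' @param guide_psd [psd_result()] of the guided phase.
#' @param video_psd [psd_result()] of the spontaneous (video) phase.
#' @param band Numeric `c(lo, hi)` in Hz; default 0.04-0.4.
#' @return An object of class `coherence_score`: list with `p01`,
#'   `h_max_guide`, `h_sum_video`, `guide_peak_location` (Hz), `band` and
#'   `above_one` flag.
#' @export
p01_index <- function(guide_psd, video_psd, band = c(0.04, 0.4)) {
  stopifnot(inherits(guide_psd, "psd_result"), inherits(video_psd, "psd_result"))
  if (guide_psd$window_name != video_psd$window_name ||
      guide_psd$pad_factor != video_psd$pad_factor)
    hrvc_error("guided and video PSDs were computed with different estimator settings",
               "hrvc_config_error")
  pk <- main_peak(guide_psd, band)
  hs <- local_peak_heights(video_psd, band)
  if (length(hs) == 0)
    hrvc_error("no peaks in the video-phase PSD band: P0.1 undefined",
               "hrvc_undefined_score")
  h_sum <- sum(hs)
  structure(list(p01 = pk$height / h_sum,
                 h_max_guide = pk$height, h_sum_video = h_sum,
                 guide_peak_location = pk$location, band = band,
                 above_one = pk$height / h_sum > 1),
            class = "coherence_score")
}

#' @export
print.coherence_score <- function(x, ...) {
  cat(sprintf("<coherence_score> P0.1 = %.3f (guided peak %.4g at %.3f Hz / video sum %.4g)%s\n",
              x$p01, x$h_max_guide, x$guide_peak_location, x$h_sum_video,
              if (x$above_one) " [> 1]" else ""))
  invisible(x)
}
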