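# Emulation of the breathing-guidance device: the pacing waveform and the
# per-phase heart-rate smoothness rule behind the visual biofeedback.

#' Guidance waveform intensity
#'
#' The device paces breathing at 0.1 Hz with a 10-s periodic triangle:
#' intensity (light level / vibration frequency) rises 0 to 1 over the 5-s
#' inspiration and falls back over the 5-s expiration.
#'
#' @param t Time(s) in seconds, >= 0; vectorized.
#' @return Intensity in `[0, 1]`.
#' @examples
#' guidance_waveform(c(0, 2.5, 5, 10))
#' @export
guidance_waveform <- function(t) {
  if (any(t < 0)) hrvc_error("t must be >= 0", "hrvc_config_error")
  tm <- t %% 10
  ifelse(tm < 5, tm / 5, 2 - tm / 5)
}

#' Alternating 5-s inspiration/expiration phase windows
#'
#' @param duration_s Session duration (s); tiled by 5-s phases, inspiration
#'   first.
#' @param start Start time (s) of the first phase.
#' @return Data frame with columns `start`, `duration`, `kind`.
#' @export
phase_windows <- function(duration_s, start = 0) {
  n <- floor(duration_s / 5)
  data.frame(start = start + 5 * (seq_len(n) - 1), duration = 5,
             kind = rep_len(c("inspiration", "expiration"), n))
}

#' Per-phase heart-rate smoothness verdicts
#'
#' The device's biofeedback rule: within each 5-s phase, the beat-wise heart
#' rate (60000 / RR) must rise monotonically during inspiration and fall
#' during expiration. A consecutive-beat pair breaking the required direction
#' by more than `hr_tol_bpm` counts as one violation; the phase is smooth
#' when the violation count does not exceed `tolerance`. Phases containing
#' fewer than 2 beats are flagged indeterminate (`smooth = NA`).
#'
#' @param rr An [rr_series()] covering the phase span.
#' @param phases Data frame from [phase_windows()]; defaults to tiling the
#'   RR series span starting at its first beat.
#' @param tolerance Allowed violations per phase (default 0).
#' @param hr_tol_bpm Equality tolerance in beats/min guarding against
#'   floating-point ties (default 0.1).
#' @return Data frame with one row per phase: `start`, `kind`, `n_beats`,
#'   `violation_count`, `smooth` (logical, `NA` when indeterminate).
#' @export
phase_smoothness <- function(rr, phases = NULL, tolerance = 0,
                             hr_tol_bpm = 0.1) {
  stopifnot(inherits(rr, "rr_series"))
  if (is.null(phases))
    phases <- phase_windows(diff(range(rr$beat_times)), start = rr$beat_times[1])
  hr <- 60000 / rr$rr_ms
  tt <- rr$beat_times[-length(rr$beat_times)]
  res <- lapply(seq_len(nrow(phases)), function(i) {
    s <- phases$start[i]
    sel <- tt >= s & tt < s + phases$duration[i]
    m <- sum(sel)
    if (m < 2L)
      return(data.frame(start = s, kind = phases$kind[i], n_beats = m,
                        violation_count = NA_integer_, smooth = NA))
    d <- diff(hr[sel])
    viol <- if (phases$kind[i] == "inspiration") sum(d < -hr_tol_bpm)
            else sum(d > hr_tol_bpm)
    data.frame(start = s, kind = phases$kind[i], n_beats = m,
               violation_count = viol, smooth = viol <= tolerance)
  })
  do.call(rbind, res)
}
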