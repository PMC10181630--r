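#' Configuration for the synthetic cardiorespiratory generator
#'
#' Parameters of the simulated physiology. The instantaneous RR interval is
#' modelled as
#' \deqn{RR(t) = \mu + A_{rsa}\sin(2\pi\phi(t) + \psi) +
#'   A_{mayer}\sin(2\pi f_m t + \phi_0) + \epsilon,}
#' where \eqn{\phi(t)} integrates an instantaneous breathing frequency that
#' performs a seeded bounded random walk around `breath_freq_hz` (SD
#' `breath_jitter_sd_hz`, clipped at 3 SD), \eqn{\epsilon} is white
#' beat-to-beat noise, and \eqn{\psi} phase-locks the respiratory sinus
#' arrhythmia to the pacing device (the default `pi/2` makes heart rate rise
#' during the 5-s inspiration half-cycle).
#'
#' @param duration_s Recording duration in seconds (> 0). Defaults to the
#'   5-min guided-breathing phase; use 480 for the 8-min spontaneous phase.
#' @param mean_rr_ms Mean RR interval (ms, > 0).
#' @param rsa_amp_ms Amplitude of the respiratory sinus arrhythmia
#'   modulation (ms).
#' @param breath_freq_hz Target breathing frequency (Hz, in (0, 0.5)):
#'   0.1 when guided, typically 0.2-0.3 when spontaneous.
#' @param breath_jitter_sd_hz SD of the slow random drift of the
#'   instantaneous breathing frequency (Hz); models human tracking error.
#' @param mayer_amp_ms Amplitude of the Mayer-wave (baroreflex) modulation (ms).
#' @param mayer_freq_hz Mayer-wave frequency (Hz), canonically 0.1.
#' @param noise_sd_ms SD of white beat-to-beat noise (ms).
#' @param ectopic_rate_per_min Expected ectopic-beat rate (1/min) applied by
#'   [generate_cohort()]; [generate_rr_series()] itself returns a clean series.
#' @param resp_noise_sd SD of additive noise on the respiration waveform
#'   (amplitude units; the breathing oscillation has unit amplitude).
#' @param rsa_phase_rad Phase offset (rad) of the RSA modulation relative to
#'   the pacing cycle.
#' @param seed Integer seed; identical configurations and seeds give
#'   identical output, element-wise.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 300, mean_rr_ms = 850, rsa_amp_ms = 60,
                         breath_freq_hz = 0.1, breath_jitter_sd_hz = 0,
                         mayer_amp_ms = 0, mayer_freq_hz = 0.1,
                         noise_sd_ms = 0, ectopic_rate_per_min = 0,
                         resp_noise_sd = 0.05, rsa_phase_rad = pi / 2,
                         seed = 1L) {
  check_scalar(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_scalar(mean_rr_ms, "mean_rr_ms", min = 0, strict_min = TRUE)
  check_scalar(rsa_amp_ms, "rsa_amp_ms", min = 0)
  check_scalar(breath_freq_hz, "breath_freq_hz", min = 0, max = 0.5,
               strict_min = TRUE, strict_max = TRUE)
  check_scalar(breath_jitter_sd_hz, "breath_jitter_sd_hz", min = 0)
  check_scalar(mayer_amp_ms, "mayer_amp_ms", min = 0)
  check_scalar(mayer_freq_hz, "mayer_freq_hz", min = 0, strict_min = TRUE)
  check_scalar(noise_sd_ms, "noise_sd_ms", min = 0)
  check_scalar(ectopic_rate_per_min, "ectopic_rate_per_min", min = 0)
  check_scalar(resp_noise_sd, "resp_noise_sd", min = 0)
  check_scalar(rsa_phase_rad, "rsa_phase_rad")
  check_scalar(seed, "seed")
  if (rsa_amp_ms + mayer_amp_ms + 4 * noise_sd_ms >= mean_rr_ms)
    config_error("mean_rr_ms",
                 paste("must exceed rsa_amp_ms + mayer_amp_ms + 4*noise_sd_ms",
                       "so RR intervals stay positive"))
  structure(list(duration_s = duration_s, mean_rr_ms = mean_rr_ms,
                 rsa_amp_ms = rsa_amp_ms, breath_freq_hz = breath_freq_hz,
                 breath_jitter_sd_hz = breath_jitter_sd_hz,
                 mayer_amp_ms = mayer_amp_ms, mayer_freq_hz = mayer_freq_hz,
                 noise_sd_ms = noise_sd_ms,
                 ectopic_rate_per_min = ectopic_rate_per_min,
                 resp_noise_sd = resp_noise_sd,
                 rsa_phase_rad = rsa_phase_rad,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Breathing phase phi(t) on a dense grid. The instantaneous frequency
# performs a mean-reverting bounded random walk around breath_freq_hz: an
# AR(1) step toward the target (relaxation time tau = 10 s, one pacing
# cycle, modelling the subject re-synchronizing each breath) with stationary
# SD breath_jitter_sd_hz, clipped to +/- 3 SD and to physiological bounds.
# Consumes RNG draws even when jitter is 0, so callers sharing a seed stay
# aligned.
breathing_phase <- function(config, dt = 0.25, tau = 10) {
  tg <- seq(0, config$duration_s + dt, by = dt)
  n <- length(tg)
  f0 <- config$breath_freq_hz
  sdj <- config$breath_jitter_sd_hz
  a <- exp(-dt / tau)
  steps <- stats::rnorm(n - 1L, 0, if (sdj > 0) sdj * sqrt(1 - a^2) else 0)
  if (sdj > 0) {
    dev <- stats::filter(steps, a, method = "recursive")
    f <- clamp(f0 + c(0, as.numeric(dev)),
               max(0.02, f0 - 3 * sdj), min(0.45, f0 + 3 * sdj))
    phi <- c(0, cumsum((f[-n] + f[-1]) / 2) * dt)
  } else {
    f <- rep(f0, n)
    phi <- f0 * tg
  }
  list(t = tg, phi = phi, f = f, exact = sdj == 0, f0 = f0)
}

# Evaluation function for phi at arbitrary times.
phi_fun <- function(bp) {
  if (bp$exact) {
    f0 <- bp$f0
    function(t) f0 * t
  } else {
    stats::approxfun(bp$t, bp$phi, rule = 2)
  }
}

#' Generate a synthetic RR-interval series
#'
#' Places beats iteratively, `t[k+1] = t[k] + RR(t[k])/1000`, with `RR(t)`
#' the modulated interval model described in [synth_config()]. Beats cover
#' `[0, duration_s]`; the series is reproducible beat-for-beat from the seed.
#'
#' @param config A [synth_config()].
#' @return An [rr_series()].
#' @examples
#' rr <- generate_rr_series(synth_config(duration_s = 60, rsa_amp_ms = 0,
#'                                       mean_rr_ms = 1000))
#' length(rr$beat_times)  # 61 beats, 1 s apart
#' @export
generate_rr_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    bp <- breathing_phase(config)
    phi <- phi_fun(bp)
    phi0 <- stats::runif(1, 0, 2 * pi)
    n_max <- ceiling(config$duration_s * 1000 /
                       (config$mean_rr_ms - config$rsa_amp_ms -
                          config$mayer_amp_ms - 6 * config$noise_sd_ms)) + 10L
    noise <- if (config$noise_sd_ms > 0)
      stats::rnorm(n_max, 0, config$noise_sd_ms) else numeric(n_max)
    beats <- numeric(n_max)
    t <- 0
    k <- 0L
    while (t <= config$duration_s + 1e-9 && k < n_max) {
      k <- k + 1L
      beats[k] <- t
      rr <- config$mean_rr_ms +
        config$rsa_amp_ms * sin(2 * pi * phi(t) + config$rsa_phase_rad) +
        config$mayer_amp_ms * sin(2 * pi * config$mayer_freq_hz * t + phi0) +
        noise[k]
      t <- t + rr / 1000
    }
    rr_series(beats[seq_len(k)])
  })
}

#' Generate a synthetic respiration waveform
#'
#' Unit-amplitude breathing oscillation `sin(2*pi*phi(t))` plus additive
#' Gaussian noise, sharing the breathing-frequency jitter model (and, for an
#' identical seed, the exact jitter trajectory) of [generate_rr_series()].
#'
#' @param config A [synth_config()].
#' @param fs Sampling rate in Hz (>= 1 recommended; the cycle detector works
#'   on a 1 Hz grid).
#' @return A [resp_signal()] of `duration_s * fs` samples.
#' @export
generate_resp_signal <- function(config, fs = 1) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    config_error("fs", "must be a positive sampling rate in Hz")
  with_seed(config$seed, {
    bp <- breathing_phase(config)
    n <- round(config$duration_s * fs)
    tt <- (seq_len(n) - 1) / fs
    x <- sin(2 * pi * phi_fun(bp)(tt))
    if (config$resp_noise_sd > 0)
      x <- x + stats::rnorm(n, 0, config$resp_noise_sd)
    resp_signal(x, fs)
  })
}

#' Inject ectopic beats into an RR series
#'
#' At seeded random beats, scales the interval to 0.6x (early, extrasystole-
#' like beat) and the following interval to 1.4x (compensatory pause), so
#' total time is preserved within one beat. The number of injections is
#' Poisson with mean `rate_per_min * duration / 60`.
#'
#' @param rr An [rr_series()].
#' @param rate_per_min Expected injections per minute (>= 0).
#' @param seed Integer seed.
#' @return A list with `rr` (modified series), `indices` (all modified
#'   interval indices, i.e. both members of each early-beat/pause pair) and
#'   `onsets` (the first index of each pair).
#' @export
inject_ectopics <- function(rr, rate_per_min, seed = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  check_scalar(rate_per_min, "rate_per_min", min = 0)
  n <- length(rr$rr_ms)
  if (rate_per_min == 0)
    return(list(rr = rr, indices = integer(0), onsets = integer(0)))
  dur_min <- diff(range(rr$beat_times)) / 60
  with_seed(seed, {
    n_inj <- stats::rpois(1, rate_per_min * dur_min)
    candidates <- seq(2L, n - 1L)
    if (n_inj > floor(length(candidates) / 3))
      hrvc_error("ectopic rate too high: modified beats would overlap",
                 "hrvc_config_error")
    onsets <- integer(0)
    if (n_inj > 0) {
      pool <- sample(candidates)
      for (k in pool) {
        if (length(onsets) >= n_inj) break
        if (all(abs(k - onsets) > 2L)) onsets <- c(onsets, k)
      }
      onsets <- sort(onsets)
    }
    new_rr <- rr$rr_ms
    new_rr[onsets] <- 0.6 * new_rr[onsets]
    new_rr[onsets + 1L] <- 1.4 * new_rr[onsets + 1L]
    beats <- rr$beat_times[1] + c(0, cumsum(new_rr)) / 1000
    list(rr = rr_series(beats, rr$corrected_fraction),
         indices = sort(c(onsets, onsets + 1L)),
         onsets = onsets)
  })
}

#' Configuration for a synthetic cohort
#'
#' Defines group sizes and the per-condition tracking-error parameters used
#' by [generate_cohort()]. Group-size defaults follow the guided-breathing
#' study design this generator emulates (11 visual, 8 haptic, 13
#' visuo-haptic). Condition defaults are calibrated so that tighter pacing
#' (visuo-haptic < haptic < visual tracking jitter) yields the qualitative
#' ordering of guided-phase coherence scores; the haptic condition carries a
#' larger between-subject RSA spread.
#'
#' @param n_visual,n_haptic,n_visuo_haptic Participants per condition (>= 1).
#' @param condition_params Data frame with columns `condition`,
#'   `breath_jitter_sd_hz`, `rsa_amp_mean_ms`, `rsa_amp_sd_ms`; one row per
#'   condition.
#' @param guided_duration_s,video_duration_s Phase durations (s): 5-min
#'   guided breathing, 8-min spontaneous video viewing.
#' @param mean_rr_ms,mayer_amp_ms,noise_sd_ms Shared physiology parameters.
#' @param video_breath_freq_hz,video_breath_jitter_sd_hz,video_rsa_amp_ms
#'   Spontaneous-phase breathing parameters (0.2-0.3 Hz RSA plus the 0.1 Hz
#'   Mayer component).
#' @param ectopic_rate_per_min Ectopic injection rate applied to both phases.
#' @param seed Master seed; per-participant seeds are derived from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_visual = 11, n_haptic = 8, n_visuo_haptic = 13,
                          condition_params = default_condition_params(),
                          guided_duration_s = 300, video_duration_s = 480,
                          mean_rr_ms = 850, mayer_amp_ms = 25,
                          noise_sd_ms = 5,
                          video_breath_freq_hz = 0.25,
                          video_breath_jitter_sd_hz = 0.03,
                          video_rsa_amp_ms = 45,
                          ectopic_rate_per_min = 0.5,
                          seed = 1L) {
  for (f in c("n_visual", "n_haptic", "n_visuo_haptic"))
    check_scalar(get(f), f, min = 1)
  stopifnot(is.data.frame(condition_params),
            all(c("condition", "breath_jitter_sd_hz", "rsa_amp_mean_ms",
                  "rsa_amp_sd_ms") %in% names(condition_params)))
  if (any(condition_params$rsa_amp_sd_ms < 0) ||
      any(condition_params$breath_jitter_sd_hz < 0))
    config_error("condition_params", "SDs must be >= 0")
  structure(list(n = c(visual = n_visual, haptic = n_haptic,
                       `visuo-haptic` = n_visuo_haptic),
                 condition_params = condition_params,
                 guided_duration_s = guided_duration_s,
                 video_duration_s = video_duration_s,
                 mean_rr_ms = mean_rr_ms, mayer_amp_ms = mayer_amp_ms,
                 noise_sd_ms = noise_sd_ms,
                 video_breath_freq_hz = video_breath_freq_hz,
                 video_breath_jitter_sd_hz = video_breath_jitter_sd_hz,
                 video_rsa_amp_ms = video_rsa_amp_ms,
                 ectopic_rate_per_min = ectopic_rate_per_min,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-condition tracking parameters
#'
#' Visual guidance has the loosest breathing-frequency tracking, adding
#' haptic cues tightens it, and the combined condition is tightest; the
#' haptic-alone condition has the widest between-subject spread of RSA
#' amplitude (mirroring heterogeneous sensitivity to vibration cues).
#'
#' @return A data frame with one row per guidance condition.
#' @export
default_condition_params <- function() {
  data.frame(condition = c("visual", "haptic", "visuo-haptic"),
             breath_jitter_sd_hz = c(0.014, 0.007, 0.005),
             rsa_amp_mean_ms = c(60, 60, 60),
             rsa_amp_sd_ms = c(8, 15, 8))
}

#' Generate a synthetic cohort
#'
#' For every participant, generates a spontaneous-breathing video phase and a
#' 0.1 Hz guided phase (RR series plus respiration waveform each), with
#' condition-specific tracking jitter and a participant-specific RSA
#' amplitude. Ectopic beats are injected into both RR series. All randomness
#' derives from the master seed through per-participant seeds, so cohorts are
#' reproducible beat-for-beat.
#'
#' @param config A [cohort_config()].
#' @return An object of class `hrv_cohort`: a list with `participants` (each
#'   holding `id`, `condition`, `seed`, and `guided`/`video` sublists with
#'   `rr` and `resp`) and a `manifest` data frame.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  participants <- list()
  rows <- list()
  idx <- 0L
  for (cond in names(config$n)) {
    cp <- config$condition_params[config$condition_params$condition == cond, ]
    if (nrow(cp) != 1L)
      config_error("condition_params", sprintf("must have one row for '%s'", cond))
    for (j in seq_len(config$n[[cond]])) {
      idx <- idx + 1L
      pseed <- (config$seed + 7919L * idx) %% 2147483647L
      rsa_i <- with_seed(pseed, max(5, stats::rnorm(1, cp$rsa_amp_mean_ms,
                                                    cp$rsa_amp_sd_ms)))
      guided_cfg <- synth_config(
        duration_s = config$guided_duration_s, mean_rr_ms = config$mean_rr_ms,
        rsa_amp_ms = rsa_i, breath_freq_hz = 0.1,
        breath_jitter_sd_hz = cp$breath_jitter_sd_hz,
        mayer_amp_ms = config$mayer_amp_ms, noise_sd_ms = config$noise_sd_ms,
        resp_noise_sd = 0.1, seed = pseed + 1L)
      video_cfg <- synth_config(
        duration_s = config$video_duration_s, mean_rr_ms = config$mean_rr_ms,
        rsa_amp_ms = config$video_rsa_amp_ms,
        breath_freq_hz = config$video_breath_freq_hz,
        breath_jitter_sd_hz = config$video_breath_jitter_sd_hz,
        mayer_amp_ms = config$mayer_amp_ms, noise_sd_ms = config$noise_sd_ms,
        resp_noise_sd = 0.1, seed = pseed + 2L)
      g_rr <- generate_rr_series(guided_cfg)
      v_rr <- generate_rr_series(video_cfg)
      if (config$ectopic_rate_per_min > 0) {
        g_rr <- inject_ectopics(g_rr, config$ectopic_rate_per_min, pseed + 3L)$rr
        v_rr <- inject_ectopics(v_rr, config$ectopic_rate_per_min, pseed + 4L)$rr
      }
      id <- sprintf("P%02d", idx)
      participants[[id]] <- list(
        id = id, condition = cond, seed = pseed,
        guided = list(rr = g_rr, resp = generate_resp_signal(guided_cfg, fs = 1)),
        video = list(rr = v_rr, resp = generate_resp_signal(video_cfg, fs = 1)))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = id, condition = cond,
        phase = c("video", "guided"), seed = pseed)
    }
  }
  structure(list(participants = participants,
                 manifest = do.call(rbind, rows),
                 config = config),
            class = "hrv_cohort")
}

#' @export
print.hrv_cohort <- function(x, ...) {
  tab <- table(vapply(x$participants, `[[`, "", "condition"))
  cat(sprintf("<hrv_cohort> %d participants (%s)\n",
              length(x$participants),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}
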