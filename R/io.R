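# Plain-text file formats: RR series, respiration waveforms, cohort
# manifests. All files are UTF-8 CSV with a header row.

#' Write / read an RR-interval series
#'
#' Two columns: `beat_time_s`, `rr_ms` (the interval starting at that beat;
#' `NA` on the last row).
#'
#' @param rr An [rr_series()].
#' @param path File path.
#' @return `write_rr_file` returns `path` invisibly; `read_rr_file` returns
#'   an [rr_series()].
#' @export
write_rr_file <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  utils::write.csv(data.frame(beat_time_s = rr$beat_times,
                              rr_ms = c(rr$rr_ms, NA)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_file
#' @export
read_rr_file <- function(path) {
  df <- read_checked_csv(path, c("beat_time_s", "rr_ms"))
  rr_series(df$beat_time_s)
}

#' Write / read a respiration waveform
#'
#' Two columns: `time_s`, `amplitude`; the sampling rate is recovered from
#' the (required, uniform) time spacing.
#'
#' @param resp A [resp_signal()].
#' @param path File path.
#' @return `write_resp_file` returns `path` invisibly; `read_resp_file`
#'   returns a [resp_signal()].
#' @export
write_resp_file <- function(resp, path) {
  stopifnot(inherits(resp, "resp_signal"))
  tt <- resp$start_time + (seq_along(resp$samples) - 1) / resp$fs
  utils::write.csv(data.frame(time_s = tt, amplitude = resp$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_resp_file
#' @export
read_resp_file <- function(path) {
  df <- read_checked_csv(path, c("time_s", "amplitude"))
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    hrvc_error(sprintf("%s: time_s must be uniformly spaced", path),
               "hrvc_parse_error")
  resp_signal(df$amplitude, fs = 1 / dt[1], start_time = df$time_s[1])
}

read_checked_csv <- function(path, required_cols) {
  if (!file.exists(path))
    hrvc_error(sprintf("file not found: %s", path), "hrvc_parse_error")
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) hrvc_error(
                   sprintf("%s: %s", path, conditionMessage(e)), "hrvc_parse_error"))
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0)
    hrvc_error(sprintf("%s: missing column(s) %s (line 1)", path,
                       paste(missing, collapse = ", ")), "hrvc_parse_error")
  for (cl in required_cols) {
    v <- df[[cl]]
    bad <- which(!is.na(v) & !is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad) > 0)
      hrvc_error(sprintf("%s: non-numeric value in column '%s' (line %d)",
                         path, cl, bad[1] + 1L), "hrvc_parse_error")
    df[[cl]] <- as.numeric(v)
  }
  df
}

#' Write a synthetic cohort to disk
#'
#' One RR file and one respiration file per participant and phase, plus a
#' `manifest.csv` with columns `participant_id`, `condition`, `phase`,
#' `rr_file`, `resp_file`, `seed` (paths relative to the manifest).
#'
#' @param cohort An `hrv_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in cohort$participants) {
    for (phase in c("video", "guided")) {
      rr_file <- sprintf("%s_%s_rr.csv", p$id, phase)
      resp_file <- sprintf("%s_%s_resp.csv", p$id, phase)
      write_rr_file(p[[phase]]$rr, file.path(dir, rr_file))
      write_resp_file(p[[phase]]$resp, file.path(dir, resp_file))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = p$id, condition = p$condition, phase = phase,
        rr_file = rr_file, resp_file = resp_file, seed = p$seed)
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read and validate a cohort manifest
#'
#' Checks that required columns are present, that every referenced file
#' exists, that participant ids are unique within a phase, and that every
#' participant has both a `video` and a `guided` phase.
#'
#' @param path Path to `manifest.csv`.
#' @return The manifest data frame, with the manifest directory attached as
#'   attribute `"dir"`.
#' @export
read_manifest <- function(path) {
  req <- c("participant_id", "condition", "phase", "rr_file", "resp_file", "seed")
  if (!file.exists(path))
    hrvc_error(sprintf("file not found: %s", path), "hrvc_parse_error")
  df <- utils::read.csv(path)
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    hrvc_error(sprintf("%s: missing column(s) %s (line 1)", path,
                       paste(missing, collapse = ", ")), "hrvc_parse_error")
  dir <- dirname(path)
  for (i in seq_len(nrow(df))) {
    for (cl in c("rr_file", "resp_file")) {
      f <- file.path(dir, df[[cl]][i])
      if (!file.exists(f))
        hrvc_error(sprintf("%s: referenced file '%s' not found (line %d)",
                           path, df[[cl]][i], i + 1L), "hrvc_parse_error")
    }
  }
  if (any(!df$phase %in% c("video", "guided")))
    hrvc_error(sprintf("%s: phase must be 'video' or 'guided'", path),
               "hrvc_parse_error")
  if (anyDuplicated(df[c("participant_id", "phase")]))
    hrvc_error(sprintf("%s: duplicate participant/phase rows", path),
               "hrvc_parse_error")
  both <- tapply(df$phase, df$participant_id,
                 function(p) all(c("video", "guided") %in% p))
  if (!all(both))
    hrvc_error(sprintf("%s: participant(s) missing a phase: %s", path,
                       paste(names(both)[!both], collapse = ", ")),
               "hrvc_parse_error")
  attr(df, "dir") <- dir
  df
}
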