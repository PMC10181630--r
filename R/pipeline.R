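# End-to-end pipeline driver and group report.

# Artifact correction -> 4 Hz resampling -> smoothness-priors detrending ->
# PSD for one phase.
process_phase <- function(rr, lambda, fs_tach, psd_window, pad_factor) {
  idx <- detect_artifacts(rr)
  rr_c <- suppressWarnings(correct_artifacts(rr, idx))
  tach <- resample_tachogram(rr_c, fs = fs_tach)
  det <- smoothness_priors_detrend(tach, lambda = lambda)
  list(rr = rr_c, tach = det,
       psd = compute_psd(det, window = psd_window, pad_factor = pad_factor))
}

#' Run the full coherence pipeline over a cohort
#'
#' For each participant: artifact detection/correction, 4 Hz cubic-spline
#' resampling, smoothness-priors detrending (`lambda = 300`), PSD estimation
#' for both phases, dominant-peak metrics and HRV-cycle RMSError on the
#' guided phase, respiratory-cycle RMSError (with the signal-to-noise
#' exclusion guard), and the P0.1 index of the guided against the video
#' phase. Per-participant failures become excluded rows with a reason; they
#' never abort the cohort.
#'
#' @param cohort An `hrv_cohort` from [generate_cohort()], or a manifest data
#'   frame from [read_manifest()] (files are loaded relative to the manifest
#'   directory).
#' @param lambda Detrending smoothing parameter.
#' @param fs_tach Tachogram sampling rate (Hz).
#' @param band PSD analysis band (Hz).
#' @param target_s Resonance target cycle duration (s).
#' @param trim Cycles trimmed from each end before the RMSError.
#' @param psd_window,pad_factor PSD estimator settings (shared by both
#'   phases).
#' @return A `results_table` data frame with one row per participant:
#'   `participant_id`, `condition`, `rmse_hrv_s`, `rmse_resp_s`,
#'   `resp_excluded_reason`, `peak_location_hz`, `peak_height`, `mphw_hz`,
#'   `p01`, `corrected_fraction`, `excluded_reason`.
#' @export
run_pipeline <- function(cohort, lambda = 300, fs_tach = 4,
                         band = c(0.04, 0.4), target_s = 10, trim = c(0L, 0L),
                         psd_window = "hann", pad_factor = 4) {
  participants <- pipeline_inputs(cohort)
  rows <- lapply(participants, function(p) {
    row <- data.frame(participant_id = p$id, condition = p$condition,
                      rmse_hrv_s = NA_real_, rmse_resp_s = NA_real_,
                      resp_excluded_reason = NA_character_,
                      peak_location_hz = NA_real_, peak_height = NA_real_,
                      mphw_hz = NA_real_, p01 = NA_real_,
                      corrected_fraction = NA_real_,
                      excluded_reason = NA_character_)
    tryCatch({
      g <- process_phase(p$guided$rr, lambda, fs_tach, psd_window, pad_factor)
      v <- process_phase(p$video$rr, lambda, fs_tach, psd_window, pad_factor)
      pk <- main_peak(g$psd, band)
      row$peak_location_hz <- pk$location
      row$peak_height <- pk$height
      row$mphw_hz <- pk$mphw
      row$corrected_fraction <- g$rr$corrected_fraction
      row$rmse_hrv_s <- rms_error(detect_hrv_cycles(g$tach), target_s, trim)$rmse
      row$p01 <- p01_index(g$psd, v$psd, band)$p01
      row <- tryCatch({
        cyc <- detect_resp_cycles(p$guided$resp)
        row$rmse_resp_s <- rms_error(cyc, target_s, trim)$rmse
        row
      }, hrvc_excluded_series = function(e) {
        row$resp_excluded_reason <- conditionMessage(e)
        row
      })
      row
    }, hrvc_error = function(e) {
      row$excluded_reason <- conditionMessage(e)
      row
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("results_table", "data.frame")
  out
}

# Normalize the run_pipeline input to a list of participants with loaded
# rr/resp objects.
pipeline_inputs <- function(cohort) {
  if (inherits(cohort, "hrv_cohort")) return(cohort$participants)
  if (is.data.frame(cohort)) {
    dir <- attr(cohort, "dir")
    if (is.null(dir))
      hrvc_error("manifest data frame must come from read_manifest()",
                 "hrvc_config_error")
    ids <- unique(cohort$participant_id)
    return(lapply(ids, function(id) {
      sub <- cohort[cohort$participant_id == id, ]
      load_phase <- function(ph) {
        r <- sub[sub$phase == ph, ]
        list(rr = read_rr_file(file.path(dir, r$rr_file[1])),
             resp = read_resp_file(file.path(dir, r$resp_file[1])))
      }
      list(id = id, condition = sub$condition[1],
           guided = load_phase("guided"), video = load_phase("video"))
    }))
  }
  hrvc_error("cohort must be an hrv_cohort or a manifest data frame",
             "hrvc_config_error")
}

#' Group-level statistical report for a pipeline metric
#'
#' Applies Tukey fence correction within each condition, then runs the
#' one-way ANOVA across conditions, Holm-corrected pairwise t tests,
#' pairwise JZS log Bayes factors, and the normality/homogeneity checks.
#'
#' @param results A `results_table` from [run_pipeline()].
#' @param metric Column to analyze (e.g. `"p01"`, `"rmse_hrv_s"`).
#' @param correct_outliers Apply [tukey_outlier_correct()] per condition.
#' @return An object of class `hrvc_group_report` (printable as plain text):
#'   list with `metric`, `n`, `anova`, `holm`, `bayes`, `assumptions`.
#' @export
group_report <- function(results, metric = "p01", correct_outliers = TRUE) {
  stopifnot(is.data.frame(results), metric %in% names(results))
  keep <- !is.na(results[[metric]])
  values <- results[[metric]][keep]
  group <- factor(results$condition[keep])
  if (correct_outliers)
    for (g in levels(group))
      values[group == g] <- tukey_outlier_correct(values[group == g])
  bayes <- holm_pairwise(values, group)[, c("group1", "group2")]
  bayes$log_bf10 <- apply(bayes, 1, function(pr)
    jzs_log_bf(values[group == pr[1]], values[group == pr[2]]))
  structure(list(metric = metric, n = table(group),
                 means = tapply(values, group, mean),
                 sds = tapply(values, group, stats::sd),
                 anova = anova_oneway(values, group),
                 holm = holm_pairwise(values, group),
                 bayes = bayes,
                 assumptions = assumption_checks(values, group)),
            class = "hrvc_group_report")
}

#' @export
print.hrvc_group_report <- function(x, ...) {
  cat(sprintf("Group report for '%s'\n", x$metric))
  for (g in names(x$n))
    cat(sprintf("  %-12s n = %2d  mean = %.4g  sd = %.4g\n",
                g, x$n[[g]], x$means[[g]], x$sds[[g]]))
  cat(sprintf("ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  cat("Holm-corrected pairwise t tests:\n")
  for (i in seq_len(nrow(x$holm)))
    cat(sprintf("  %s vs %s: t = %.3f, p_holm = %.4g\n",
                x$holm$group1[i], x$holm$group2[i], x$holm$t[i], x$holm$p_holm[i]))
  cat("Pairwise log(BF10):\n")
  for (i in seq_len(nrow(x$bayes)))
    cat(sprintf("  %s vs %s: %.3f\n",
                x$bayes$group1[i], x$bayes$group2[i], x$bayes$log_bf10[i]))
  lv <- x$assumptions$levene
  cat(sprintf("Levene (center = mean): F(%d, %d) = %.3f, p = %.4g\n",
              lv$df[1], lv$df[2], lv$F, lv$p))
  invisible(x)
}
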