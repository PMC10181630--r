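# hrvcoherence

Quantifies **cardiac coherence** — the heart-rate-variability (HRV) state in
which one large, smooth oscillation near 0.1 Hz dominates the RR-interval
signal — achieved during **resonance frequency breathing** (paced at 6
breaths/min, 5 s inspiration / 5 s expiration). It is aimed at researchers
analyzing HRV-biofeedback protocols in which a spontaneous-breathing baseline
phase (e.g. watching a neutral video for 8 min) is followed by a guided
breathing phase (5 min at 0.1 Hz) under visual, haptic or combined guidance.

From a beat-event RR series and a chest-belt respiration waveform the package
computes, per participant:

* **RMSError** of the oscillation cycle durations against the 10-s target,

  RMSError = sqrt( (1/N) Σₙ (xₙ − 10)² ),

  with xₙ the n-th peak-to-peak cycle duration (s) of the HRV or respiratory
  oscillation;
* **dominant PSD peak** descriptors in the 0.04–0.4 Hz band — location (Hz),
  height (ms²/Hz), and mid-peak-height width (MPHW, Hz) — from a Hann-tapered,
  zero-padded single-segment periodogram of the 4 Hz cubic-spline tachogram
  after smoothness-priors detrending (λ = 300 ⟷ 0.042 Hz cutoff);
* **P₀.₁** = H\_max(guided) / Σ H(video), the ratio of the guided-phase
  maximal peak height to the cumulative sum of local peak heights in
  0.04–0.4 Hz of the spontaneous phase — near 1 when the band's power has
  concentrated at the guided frequency.

Supporting stages: ectopic-beat detection/correction (median-of-neighbours
rule, linear interpolation repair), respiratory cycle extraction with a
signal-to-noise exclusion guard, an emulation of the guidance device's
per-phase heart-rate monotonicity (smoothness) rule, group statistics (Tukey
fence winsorization, one-way ANOVA, Holm post hocs, pairwise JZS log Bayes
factors, Shapiro–Wilk/Levene checks), and a fully seeded synthetic
cardiorespiratory generator (RSA, Mayer waves, breathing-frequency tracking
jitter, ectopics) so the entire pipeline is testable without recorded human
data.

## Worked example

```r
library(hrvcoherence)

cfg     <- cohort_config(n_visual = 8, n_haptic = 8, n_visuo_haptic = 8, seed = 2026)
cohort  <- generate_cohort(cfg)          # seeded synthetic cohort, both phases
results <- run_pipeline(cohort)          # correction -> 4 Hz -> detrend -> PSD -> metrics
head(results[, c("participant_id", "condition", "rmse_hrv_s", "peak_location_hz", "p01")], 3)
#>     participant_id condition rmse_hrv_s peak_location_hz   p01
#> P01            P01    visual      1.598            0.108 0.288
#> P02            P02    visual      1.397            0.101 0.591
#> P03            P03    visual      1.272            0.100 0.367

group_report(results, metric = "p01")
#> Group report for 'p01'
#>   haptic       n =  8  mean = 0.9365  sd = 0.6625
#>   visual       n =  8  mean = 0.4447  sd = 0.1445
#>   visuo-haptic n =  8  mean = 0.9694  sd = 0.3545
#> ANOVA: F(2, 21) = 3.541, p = 0.04728
#> Holm-corrected pairwise t tests:
#>   haptic vs visual: t = 2.052, p_holm = 0.1188
#>   haptic vs visuo-haptic: t = -0.124, p_holm = 0.9032
#>   visual vs visuo-haptic: t = -3.877, p_holm = 0.005028
#> Pairwise log(BF10):
#>   haptic vs visual: 0.453
#>   haptic vs visuo-haptic: -0.844
#>   visual vs visuo-haptic: 2.977
#> Levene (center = mean): F(2, 21) = 4.738, p = 0.02003
```

Reading the output: every participant's guided-phase HRV peak sits at
~0.100 Hz (coherence was reached in all conditions), but *how completely*
power concentrated there differs — mean P₀.₁ is about twice as high under
visuo-haptic guidance (0.97) as under visual-only guidance (0.44), the Holm-
corrected visual vs visuo-haptic contrast is significant (p ≈ 0.005, log
BF₁₀ ≈ 3), RMSError is largest in the visual group, and the haptic group
shows the widest between-subject spread. The detrending filter's cutoff:

```r
detrend_cutoff_frequency(300, fs = 4)
#> [1] 0.042
```

A thin command-line front end wraps the same functions
(`inst/cli/hrvc.R simulate | analyze | cohort | cutoff`), e.g.
`Rscript inst/cli/hrvc.R cutoff --lambda 300 --fs 4` prints `0.042`.

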