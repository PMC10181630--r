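---
title: "Quantifying cardiac coherence from RR intervals and respiration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac coherence from RR intervals and respiration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvcoherence)
```

## The problem

Cardiac coherence is the heart-rate-variability (HRV) state in which a single
large oscillation near 0.1 Hz dominates the RR-interval signal. It arises when
breathing is slowed to the resonance region (~6 breaths/min), so that
respiratory vagal modulation (respiratory sinus arrhythmia, RSA — normally at
the spontaneous 0.2–0.3 Hz breathing rate) superimposes on the ~0.1 Hz
baroreflex/Mayer rhythm. Guidance devices pace inspiration and expiration in
5-s halves of a 10-s cycle and may feed back whether the measured heart rhythm
is "smooth".

This package quantifies how well a participant achieved coherence during a
guided phase, relative to a preceding spontaneous-breathing (video) phase,
from two inputs: a beat-event RR series and a chest-belt respiration waveform.
Three estimators are computed per participant:

1. **RMSError** (time domain): cycle-to-cycle deviation of the HRV (or
   respiratory) oscillation period from the 10-s target,
   $\mathrm{RMSError} = \sqrt{\tfrac1N \sum_{n=1}^N (x_n - 10)^2}$,
   with $x_n$ the n-th peak-to-peak cycle duration in seconds.
2. **Dominant-peak descriptors** (frequency domain): location, height and
   mid-peak-height width (MPHW) of the maximal peak of the power spectral
   density (PSD) in the 0.04–0.4 Hz HRV band.
3. **P~0.1~** (concentration index): the guided-phase maximal peak height
   divided by the cumulative sum of the local peak heights in 0.04–0.4 Hz of
   the video-phase PSD,
   $P_{0.1} = H_{max}^{guide} / \sum_{f=0.04}^{0.4} H^{video}$.
   Values near 1 mean that power previously spread over the band has
   accumulated at the guided frequency.

## Pipeline and its choices

### Artifact handling

Beat series contain occasional ectopic beats (an early extrasystole followed
by a compensatory pause). The detector flags interval $k$ when it deviates by
more than 20% (configurable) from the median of its five nearest neighbouring
intervals. Ectopic pairs modelled as 0.6×/1.4× of the local interval deviate
by 40% and are caught; physiological RSA stays below ~10%. Flagged intervals
are replaced by linear interpolation between the nearest clean intervals and
beat times are rebuilt cumulatively; interpolating between "adjacent values"
admits several readings, and linear is the minimal one. A warning fires when
more than 2% of intervals needed correction, the level above which a
recording should be treated as suspect. The detector threshold is a
documented, automatic replacement for what is often manual visual inspection.

### Resampling and detrending

The unevenly sampled RR sequence is interpolated with a cubic spline
(intervals attributed to the interval's starting beat) and evaluated on a
uniform 4 Hz grid, clamped to the data span. Trend and very-low-frequency
content are then removed by smoothness-priors detrending: with $z$ the
mean-removed tachogram and $D_2$ the second-difference operator, the trend
estimate is $(I + \lambda^2 D_2^\top D_2)^{-1} z$ and the detrended signal is
$z$ minus that estimate, solved as a banded sparse system (O(n); verified
against a dense solve in the tests). The mean is not restored — spectral
analysis needs only the fluctuations.

`lambda` controls the cutoff. The package measures the cutoff from the
mid-record magnitude response of the equivalent high-pass operator
$L = I - (I+\lambda^2 D_2^\top D_2)^{-1}$ against complex exponentials.
"Cutoff" needs a convention: this package defines it as the frequency at
which the high-pass response first reaches $1 - e^{-1} \approx 0.632$,
equivalently where the trend estimator still passes $1/e$ of a sinusoid's
amplitude. Under this convention `lambda = 300` at 4 Hz cuts at 0.042 Hz,
the value the default settings are intended to realize, leaving the whole
0.04–0.4 Hz analysis band essentially untouched (the response at 0.1 Hz is
0.98). The more common −3 dB convention is available via the `threshold`
argument (it yields 0.046 Hz at `lambda = 300`, and 0.035 Hz at
`lambda = 500` — the latter is the value documented for that setting by
standard HRV software, which is why the package treats the two conventions
as genuinely different rather than approximations of one another).

```{r}
detrend_cutoff_frequency(300, fs = 4)
detrend_cutoff_frequency(300, fs = 4, threshold = 1 / sqrt(2))
```

### Spectral estimation

The PSD is a single-segment periodogram of the full record with a Hann taper
and density (power per Hz) scaling, zero-padded to the next power of two at
least 4× the record length. A single segment preserves the narrow resonance
peak that Welch averaging would broaden; density scaling makes the 8-min
video phase and the 5-min guided phase comparable despite different record
lengths. Peak location is refined by parabolic interpolation over the three
bins around the maximum and reported to 3 decimals; peak height is read at
the raw maximal bin so heights are comparable across records sharing a grid;
MPHW is the width at half the peak height found by linear interpolation on
each flank. The P~0.1~ denominator uses strict local maxima with no
prominence threshold (an optional prominence filter exists but defaults
off), and the numerator is the band-wide maximum with its location reported
so proximity to 0.1 Hz can be asserted separately. Whether peak "height"
should be density or band-integrated power is a genuine ambiguity for this
kind of index; density is used consistently, and since P~0.1~ is a ratio of
heights from identically configured estimators, common scale factors cancel.
Both phases are preprocessed identically (same correction, resampling and
detrending), a documented assumption.

### Cycle extraction

Oscillation cycles are successive peak-to-peak delays: local maxima with a
minimum separation (5 s for the 4 Hz tachogram, 3 s for 1 Hz respiration —
safely below the 10-s target) and topographic prominence of at least 25% of
the signal's interquartile range. Peak times are refined sub-sample by a
parabola through the peak bin and its neighbours, which removes the ±1 s
quantization a 1 Hz respiration grid would otherwise impose on 10-s cycles.
A respiration series is rejected as unusable (a classed condition, never a
silent `NA`) when the detected cycle count deviates by more than 30% from
the count expected at 0.1 Hz — the operational form of excluding chest-belt
recordings with insufficient signal-to-noise. RMSError uses all detected
cycles by default; a `trim` option excludes leading/trailing cycles when
phase-boundary transients should be ignored.

### The device smoothness rule

The guidance device's biofeedback is emulated as: within each 5-s phase, the
beat-wise heart rate (60000/RR) must increase monotonically during
inspiration and decrease during expiration; consecutive-beat pairs breaking
the required direction count as violations, with a 0.1 bpm equality band
guarding against floating-point ties. The comparison of the measured rhythm
to the expected 0.1 Hz sine is realized solely as this per-phase
monotonicity check — the minimal faithful reading of how such devices
operate; the blue-to-orange colour fade is modelled as the binary smooth
state, and rendering is out of scope.

### Group statistics

Outliers are corrected with Tukey fences ($Q_1 - 1.5\,\mathrm{IQR}$,
$Q_3 + 1.5\,\mathrm{IQR}$; type-7 linear-interpolation quartiles) by
winsorizing to the nearer fence, which preserves group sizes. The omnibus
test is a classical one-way ANOVA; post hocs are pooled-variance t tests
with Holm's step-down correction (Welch by flag); Shapiro–Wilk (per group)
and Levene (centered at the mean, via `car::leveneTest`) are reported but do
not gate the ANOVA. Bayesian evidence is summarized by pairwise two-sample
JZS Bayes factors — Cauchy prior of scale $\sqrt2/2$ on the standardized
effect, computed by numerical quadrature of the marginal likelihood ratio —
as log(BF~10~); a full multi-group Bayesian ANOVA is out of scope.

## The synthetic-physiology generator

No public recordings exist for this protocol, so every stage is exercised on
synthetic data with the statistical structure the analysis assumes:

* instantaneous RR:
  $RR(t) = \mu + A_{rsa}\sin(2\pi\phi(t)+\psi) + A_{mayer}\sin(2\pi f_m t + \phi_0) + \epsilon$,
  with beats placed iteratively $t_{k+1} = t_k + RR(t_k)/1000$ — a direct
  interval-modulation model, chosen over an integral-pulse-frequency model
  because it is simpler and sufficient for the spectral properties under
  test;
* $\phi(t)$ integrates an instantaneous breathing frequency performing a
  mean-reverting bounded random walk around the target: AR(1) reversion with
  a 10-s relaxation time (subjects re-synchronize to the pacer each breath),
  stationary SD `breath_jitter_sd_hz`, clipped at ±3 SD. Pure (non-reverting)
  random walks were rejected because they park the breathing frequency at an
  offset for the whole record, contradicting the uniform ~0.100 Hz guided
  peak locations such protocols produce;
* respiration shares the same $\phi(t)$ (identical trajectory for an
  identical seed) as a unit sine plus additive noise;
* ectopic beats: Poisson-injected 0.6×/1.4× pairs (canonical
  extrasystole/compensatory-pause shape, configurable), total time preserved
  within a beat;
* phase durations default to the emulated protocol: 8-min spontaneous video
  phase (0.25 Hz breathing), 5-min guided phase (0.1 Hz).

Cohort defaults use group sizes 11 (visual), 8 (haptic), 13 (visuo-haptic).
The per-condition tracking-jitter SDs (0.014 / 0.007 / 0.005 Hz) and the
spontaneous-phase parameters (RSA 45 ms at 0.25 Hz with 0.03 Hz jitter,
Mayer 25 ms, beat noise 5 ms, 0.5 ectopics/min) were calibrated once so the
qualitative group structure emerges — visuo-haptic guidance roughly doubling
P~0.1~ relative to visual-only, RMSError largest under visual-only — because
no distributional description of human tracking error exists to copy;
magnitudes of published group means are **not** reproduction targets, only
orderings. All randomness flows from one master seed through per-participant
streams, so cohorts are reproducible beat-for-beat.

What the generator does *not* model: baroreflex feedback (the Mayer term is
an independent additive oscillation, not a closed loop), cardiorespiratory
coupling beyond additive RSA, raw ECG/PPG waveforms, or slow non-stationary
trends beyond what detrending removes. Passing tests therefore demonstrate
the pipeline's correctness and calibration on signals with known structure,
not the physiological validity of any particular human dataset.

## Numerical choices and problem sizes

* Cutoff measurement: 2048-sample operator, one sparse solve for the
  mid-record impulse response, coarse bracket then `uniroot` to 1e−7 Hz;
  insensitive (<1%) to operator size beyond ~1024 samples.
* Peak refinement offsets are clipped to ±0.5 bin; ties in the parabola
  denominator fall back to the raw bin.
* Degenerate inputs are classed conditions: flat respiration → excluded
  series; monotone/flat density in band → no-peak; all intervals flagged →
  unrecoverable series; zero within-group variance → degenerate ANOVA.
* Test-suite simulation sizes: calibration checks use 4–10 seeded
  replicates per setting; the null-calibration (type-I error) run uses 500
  replicate cohorts of 6 participants × 3 conditions, guided phase only,
  with the RMSError metric — the rejection rate at α = 0.05 must lie in
  [0.02, 0.08]. Jitter-monotonicity checks hold the video phase fixed and
  pair guided-phase seeds across a 5-point jitter grid, isolating the
  jitter effect as the invariant demands.

## Known limitations

* The RMSError summation treats all retained cycles equally; whether a
  published analysis trimmed boundary cycles is often unclear, so `trim`
  defaults to 0 and is reported in the result object.
* P~0.1~ can exceed 1 (a guided peak taller than the summed video peaks);
  it is flagged, not clipped.
* The artifact rule is intentionally simple (median-of-neighbours); it is
  not a general arrhythmia classifier.
* Absolute peak heights depend on the estimator configuration (window,
  padding, density scaling) and should only be compared across records
  analyzed with identical settings — the `p01_index()` constructor enforces
  this.
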