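---
title: "Methods: relating spontaneous respiration to continuous parasympathetic HRV"
author: "resphrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relating spontaneous respiration to continuous parasympathetic HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(resphrv)
```

## The scientific question

During spontaneous resting breathing, which representation of the
respiratory signal carries the most information about beat-to-beat
parasympathetic (vagal) cardiac modulation: the raw belt waveform, the
breathing *depth*, or the breathing *rate*?  `resphrv` implements a
complete, testable pipeline for answering that question.  Respiration is
decomposed with the analytic signal (Hilbert transform) into an
instantaneous amplitude (depth) and an instantaneous frequency (rate);
parasympathetic activity is tracked continuously with three standard
heart-rate-variability (HRV) indices — log high-frequency (HF) power,
RMSSD, and the Poincare cardiac vagal index (CVI) — on a short sliding
window; each respiratory measure is correlated with each index within a
participant; and the Fisher-z correlations are compared across measures
with a repeated-measures ANOVA and Bonferroni-corrected pairwise tests.

Because suitable paired cardiorespiratory recordings are rarely public,
the package ships a synthetic cohort generator with controllable ground
truth, so every stage — and the group-level conclusion itself — can be
verified against a known data-generating process.

## Respiratory decomposition

A belt signal is band-limited before decomposition: drift below 0.01 Hz
and noise above 2 Hz are removed, then a 0.75 Hz low-pass leaves a
quasi-monocomponent waveform.  All three stages use the magnitude
response of an order-4 Butterworth applied with exactly zero phase, by
frequency-domain multiplication on an even-extended copy of the record.
Zero phase matters because downstream correlations are computed at zero
lag; the even extension avoids end-point discontinuities, and the
spectral construction is numerically stable at the extreme normalized
cutoff a 0.01 Hz high-pass implies at 500 Hz (transfer-function
coefficient filtering is not reliable there).  Records shorter than 30 s
are rejected: the drift filter has nothing meaningful to estimate.

The analytic signal $s_a(t) = s(t) + i\,\mathcal{H}[s](t) =
s_m(t)e^{i\varphi(t)}$ gives the instantaneous amplitude $s_m(t)$
(respiratory depth) and unwrapped phase $\varphi(t)$.  The
instantaneous frequency $s_f(t) = \frac{1}{2\pi}\frac{d\varphi}{dt}$
(respiratory rate, central differences) requires a monotone phase, but
the raw phase of a real signal dips backwards wherever the analytic
trajectory loops near the origin.  The correction iterates two steps:
decreasing phase segments are replaced by linear interpolation between
the bracketing extrema (the sample where the phase stopped increasing
and the point where it recovers — implemented as interpolation across
all samples below the running maximum), then the phase *increments* are
low-passed at 0.75 Hz and re-integrated.  Filtering increments rather
than the absolute phase avoids re-introducing drift.  Ten rounds is the
cap; the loop exits as soon as the phase is monotone (to within
$10^{-9}$ rad per step), which makes the output a true fixed point —
re-filtering a converged phase would otherwise keep eroding in-band
content because the passband gain of any real filter is slightly below
one.  A terminal monotone repair enforces the non-decreasing contract
exactly.

The sign of the frequency is inverted in the output
(`rate_inverted = -frequency`): slower breathing is the direction
physiologically expected to accompany greater vagal activity, so after
inversion all three respiratory measures are oriented the same way for
comparison.

Edge effects of filtering and of the finite-record Hilbert transform are
confined to a configurable guard band (default 10 s per end) that the
correlation stage excludes.

## ECG processing and continuous HRV

R peaks are detected with the Pan-Tompkins stages: 5–15 Hz band-pass,
five-point derivative, squaring, 150 ms moving-window integration,
adaptive dual signal/noise thresholds on both the integrated and the
band-passed signal (initialized from the first 2 s), a 200 ms
refractory period, and search-back at 1.66 times the running R-R mean.
Band-pass and integration are zero-phase/centred, so accepted peaks are
refined to the band-passed local maximum within ±75 ms with no
systematic group delay; on clean template ECG the round trip against
simulated ground truth is exact to well under 10 ms.

R-R intervals outside 250–1500 ms (inclusive bounds) are treated as
missing and repaired with a natural cubic spline over beat index
through the valid intervals; edge runs without bracketing support take
the nearest valid value, with a warning.  The repaired tachogram can be
resampled to a uniform 0.1 s grid with shape-preserving
(Fritsch–Carlson monotone Hermite) interpolation, which cannot
overshoot the local data range — overshoot in a tachogram would
manufacture spurious HF power.

Three indices are computed in a window centred on each 0.1 s grid time
(default window 5 s; centring keeps the respiratory and cardiac series
at symmetric lag):

* **log HF power** — Lomb–Scargle spectral density of the
  mean-subtracted R-R values at their irregular beat times, integrated
  over 0.15–0.40 Hz (trapezoid, 0.005 Hz grid), reported as
  $\log_{10}(P + \varepsilon)$ with $\varepsilon = 10^{-6}\,$ms².  The
  Lomb estimator is used precisely because beat-domain data are
  unevenly sampled; a documented switch computes it from the resampled
  series instead.  The density is scaled so a sinusoid of amplitude $a$
  integrates to $a^2/2$, keeping HF in ms².
* **RMSSD** — $\sqrt{\mathrm{mean}(\Delta \mathrm{RR}^2)}$, at least
  two successive differences.
* **CVI** — $\log_{10}(SD1 \times SD2)$ from the Poincare plot, with
  population SDs of the rotated coordinates
  $(\mathrm{RR}_{k+1}\mp\mathrm{RR}_k)/\sqrt{2}$, floored at
  $\varepsilon$ when degenerate.

Windows overlapping the record edges or holding fewer beats than the
per-index minimum (3 for RMSSD, 4 for HF and CVI) are *missing*, never
zero.  A 5 s window holds roughly six beats, so a single window's HF
estimate is highly variable and cannot resolve a full 0.15 Hz cycle;
the package treats the 5 s HF track as an ordinal signal (its sliding
values correlate with the true modulation) and reserves quantitative
spectral claims for long windows, where the estimator is verified
against the closed-form sinusoid power.  The window-length trade-off
can be quantified with `validate_window_choice()`, which correlates
time-averaged windowed indices with whole-record indices across
subjects.

Internally the whole track is computed without a per-window loop: every
per-window statistic, including all Lomb trigonometric sums, is a
contiguous-range difference of per-interval cumulative sums.  The
vectorized track equals the per-window estimators to machine precision
(this is asserted in the test suite).

## Group statistics

Within each subject, each respiratory measure (preprocessed waveform,
amplitude, inverted rate) is aligned to the HRV grid (direct sample
pick-off when grid times hit samples, linear interpolation otherwise —
the measures are band-limited far below the sampling rate, so the two
paths agree to rounding), guard bands and missing windows are dropped
pairwise, and Spearman correlations are computed (rank-based, so any
monotone distortion of the belt signal is irrelevant).  Cells with
fewer than 100 usable points are missing.  Correlations are Fisher-z
transformed (`atanh`), the variance-stabilizing scale on which group
comparisons are made; $|\rho|=1$ is clipped to $1-10^{-7}$ with a
warning.

Per index, the subjects x 3 matrix of z values enters a one-way
within-subject ANOVA via the direct sums-of-squares decomposition
($F = MS_{measure}/MS_{error}$ on $(k-1, (k-1)(n-1))$ df, partial
$\eta^2 = SS_m/(SS_m+SS_e)$), cross-checked in the tests against both
a brute-force oracle and `aov()` with an `Error(subject/measure)`
stratum.  No sphericity correction is applied by default — uncorrected
df are the conventional report for three levels — and a
Greenhouse–Geisser option is available.  Pairwise comparisons are
paired t tests on z differences with Bonferroni factor 3, capped at 1;
subjects with any missing cell are dropped listwise (the within-subject
decomposition needs balance).  Correlations are zero-lag only: lead/lag
structure between respiration and HRV is out of scope.  The grid is
heavily autocorrelated, so `n_pairs` overstates the effective sample
size per subject; this affects per-subject inference (not performed)
but not the group-level comparison, whose unit of analysis is the
subject.  A thinning factor is available.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with ground truth recorded on the sample grid:

* **Respiration**: $\mathrm{resp}(t) = d(t)\cos\varphi(t) + $ drift
  $+$ noise, where the depth envelope $d(t)$ and rate $r(t)$ (with
  $\dot\varphi = 2\pi r$) are independent slow processes — white noise
  low-passed at 0.05 Hz, standardized per record, scaled by
  `depth_sd` / `breath_rate_sd_hz` around their means.  Sighs (Poisson
  events, default 0.5/min) add ~2 s Gaussian envelope boosts of one
  `base_depth`.  The envelope is floored at 10% of `base_depth`
  (amplitude must stay positive for the decomposition to be
  identifiable) and the rate at 0.05 Hz.  A 0.005 Hz drift exercises
  the high-pass.
* **Beats**: integral pulse frequency modulation — a beat fires when
  $\int_0^t (1+m(u))\,\mathrm{HR}_0/60\,du$ crosses an integer.  The
  vagal modulation
  $m(t) = [g_d\,\mathrm{norm}(d) + g_r\,\mathrm{norm}(r)]\sin\varphi + m_0(t)$
  is phase-locked within the breath (RSA timing), with
  $\mathrm{norm}(x) = \min(x/\bar{x},\,2.5)$ a positive mean-normalized
  envelope: modulation *amplitude* grows monotonically with depth
  and/or rate, saturating at 2.5x the mean.  $m_0$ is band-limited
  (0.04–0.40 Hz) noise of amplitude `hrv_noise_gain`, independent of
  respiration — it keeps R-R variability alive in the uncoupled null
  scenario, where coupled and uncoupled subjects would otherwise be
  distinguishable by variance alone.  $|m| \ge 1$ is rejected naming
  the offending gain.
* **ECG**: fixed Gaussian QRS templates (SD 10 ms) at the beat times,
  small P/T bumps, white noise.  Morphology is deliberately minimal:
  it exists to exercise the detector, and detector robustness is
  probed with additive noise, not with pathological beats.

Cohorts derive per-subject seeds from a master seed by a counter-based
scheme (each subject reproducible in isolation) and jitter physiology
across subjects: heart rate SD 6 bpm (clamped to 45–110), breathing
rate SD 0.03 Hz (clamped to 0.15–0.35 Hz, the spontaneous resting
range), depth scale and depth variability log-normal with SD 0.2.
Scenarios fix the gains: `depth-coupled` $(g, 0)$, `rate-coupled`
$(0, g)$, `null` $(0, 0)$.

### Chosen constants, and why

| parameter | default | rationale |
|---|---|---|
| `base_breath_rate_hz` | 0.25 Hz | centre of the spontaneous resting range (0.2–0.3 Hz) |
| `breath_rate_sd_hz` | 0.02 Hz | slow drift, small relative to the mean, as at rest |
| `depth_sd` | 0.25 (of depth 1) | visible slow depth wandering without envelope collapse |
| `sigh_rate_per_min` | 0.5 | occasional spontaneous deep breaths |
| `mean_hr_bpm` | 70 | resting adult heart rate |
| coupling gain $g$ | 0.25 | a *moderate* coupling: the depth-coupled scenario reproduces the qualitative amplitude-over-rate ordering without saturating correlations near 1; no quantitative coupling strength is claimed |
| `hrv_noise_gain` | 0.08 | respiration-independent vagal noise; keeps null-scenario RMSSD in a plausible resting range (tens of ms) |
| HF band | 0.15–0.40 Hz | standard short-term HRV HF definition |
| R-R gates | 250–1500 ms | standard physiological plausibility range, inclusive |
| window / grid | 5 s / 0.1 s | temporal resolution vs reliability trade-off; see `validate_window_choice()` |
| guard band | 10 s | covers filter settling and Hilbert edge effects at these cutoffs |

What the generator does *not* emulate: respiratory mechanics, sympathetic
/ low-frequency dynamics beyond band-limited noise, motion artefacts,
ectopy, or realistic multi-lead ECG morphology.  Tests passing on this
generator therefore demonstrate correctness of the *pipeline* under the
assumed signal model, not robustness to every failure mode of real
recordings.

## Study-scale checks

The acceptance-level tests run three simulation studies chosen to fit
comfortably in a routine test run:

* *Type-I error*: 400 null-scenario cohorts of 33 subjects, 60 s
  records at 50 Hz, consuming the true IPFM beat times (detector
  fidelity is established separately on 500 Hz template ECG; the fast
  path isolates the statistical question from detector runtime).  The
  per-index rejection rate of the uncorrected RM-ANOVA at
  $\alpha = 0.05$ is compared with the nominal level under a binomial
  tolerance.  Short records make the per-subject Fisher-z values
  heavy-tailed (slow envelopes yield few effective degrees of freedom
  per correlation), which pushes the observed rate to the conservative
  side of nominal.
* *Ordering recovery*: one depth-coupled cohort of 33 subjects, 300 s
  records at 500 Hz, through the full path including ECG synthesis and
  detection: mean z(amplitude) must exceed mean z(rate) for all three
  indices and the amplitude-vs-rate Bonferroni comparison must be
  significant — the headline qualitative pattern.
* *Determinism*: identical master seed and configuration produce
  byte-identical correlation tables and JSON summaries (correlation
  tables are written at full double precision for exactly this
  reason).

## Numerical choices and degenerate inputs

* Analytic signal by frequency-domain construction on the full record;
  phase unwrapping with tolerance $\pi$.
* An all-zero respiration yields zero amplitude and zero phase by
  convention (with a message) rather than an error.
* Degenerate (constant) HRV windows floor at $\log_{10}\varepsilon$
  and are flagged; they are never silently zero.
* Zero error variance in the ANOVA reports $F = \infty, p = 0$;
  all-equal data report $F = 0, p = 1$.
* FFT lengths are padded (edge replication) to 5-smooth numbers so
  filtering stays $O(n \log n)$ for any record length.
* The "waveform" correlation measure is the *preprocessed* waveform —
  the signal the decomposition actually sees; the unfiltered belt
  trace can be substituted by calling `subject_correlations()` on a
  decomposition built with `preprocess = FALSE`.

## Known limitations

* The drift/noise removal is implemented as one zero-phase cascade;
  whether the original band edges were realised as a single band-pass
  or sequential filters, and with what rolloff, is a free choice here.
* The 5 s HF track is ordinal, not quantitative (see above).
* No ectopic-beat classification beyond range gating; no LF or
  sympathetic indices; no time-frequency HRV.
* Zero-lag correlations only.

## A compact worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(33, sim_config(duration_s = 300, fs = 500,
                                         seed = 7),
                          scenario = "depth-coupled")
cs <- run_cohort(cohort, run_config(), out_dir = "results")
summary(cs)
plot(cs)
```
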