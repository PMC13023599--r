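# resphrv

Which representation of spontaneous breathing best tracks
parasympathetic (vagal) cardiac activity — the raw respiratory belt
waveform, the breathing **depth**, or the breathing **rate**?

`resphrv` is an R package for researchers in cardiorespiratory and
autonomic physiology who want to answer that question on paired
respiration + ECG recordings, or to study the question's statistical
behaviour on fully synthetic cohorts with known ground truth.

## The method

For each participant:

1. **Respiratory decomposition.** The belt signal is band-limited
   (drift < 0.01 Hz and noise > 2 Hz removed, then low-passed at
   0.75 Hz, all zero-phase) and decomposed through the analytic signal
   `s_a(t) = s(t) + i H[s](t) = s_m(t) e^{i φ(t)}`: the instantaneous
   amplitude `s_m(t)` is respiratory depth, and the instantaneous
   frequency `s_f(t) = (1/2π) dφ/dt` — computed after an iterative
   monotone phase correction and sign-inverted — is respiratory rate.
2. **Continuous vagal indices.** R peaks are extracted with the
   Pan–Tompkins algorithm; R–R intervals outside 250–1500 ms are
   repaired by natural cubic splines; log HF power (Lomb–Scargle,
   0.15–0.40 Hz), RMSSD, and the Poincaré cardiac vagal index
   `CVI = log10(SD1 × SD2)` are computed in a 5 s window sliding on a
   0.1 s grid (piecewise-cubic-Hermite tachogram resampling is
   available for uniform-grid work).
3. **Within-participant correlation.** Spearman correlations between
   each respiratory measure (waveform, amplitude, inverted rate) and
   each index (HF, RMSSD, CVI), Fisher-z transformed.

At the group level, a one-way repeated-measures ANOVA per index
compares the z values across the three respiratory measures
(`F = MS_measure/MS_error`, df `(2, 2(n−1))`, partial η²), with
Bonferroni-corrected paired t tests for the three measure pairs.

A synthetic cohort generator (integral pulse frequency modulation with
the vagal modulation amplitude coupled, at configurable gain, to
respiratory depth and/or rate, phase-locked within the breath)
provides ground truth for every stage.

## Worked example

```r
library(resphrv)

cohort <- simulate_cohort(33, sim_config(duration_s = 300, fs = 500, seed = 7),
                          scenario = "depth-coupled")
cs <- run_cohort(cohort, run_config())
cs
```

```
<cohort_stats: 33 subjects, 0 excluded, alpha = 0.05>
  HF    Repeated-measures ANOVA: F(2, 64) = 369.857, p = 6.831e-36, partial eta^2 = 0.920 (n = 33)
  RMSSD Repeated-measures ANOVA: F(2, 64) = 496.263, p = 1.08e-39, partial eta^2 = 0.939 (n = 33)
  CVI   Repeated-measures ANOVA: F(2, 64) = 359.339, p = 1.596e-35, partial eta^2 = 0.918 (n = 33)
```

The main effect of respiratory measure is significant for every
parasympathetic index.  `summary(cs)` adds the pairwise tables; in this
run the mean Fisher z for instantaneous amplitude is ≈ 0.77–0.80 across
the three indices while waveform and rate sit near zero, and the
amplitude-vs-rate comparison for RMSSD has mean z difference 0.871
(SE 0.037, Bonferroni p ≈ 3.8e-21) — the generator couples vagal
modulation to depth only, and the pipeline recovers exactly that
structure.  `plot(cs)` draws the per-subject z
distributions with mean ± SE bars, and `run_cohort(..., out_dir =)`
writes correlation/ANOVA/pairwise CSVs, a JSON summary, and a run log
that echoes every analysis constant with its provenance.

Individual stages are ordinary functions with classed results:
`decompose_respiration()`, `detect_r_peaks()`,
`clean_and_interpolate_rr()`, `sliding_hrv()`, `subject_correlations()`,
`rm_anova()`, `bonferroni_pairwise()`, `validate_window_choice()`, each
with `print`/`plot` methods where useful.

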