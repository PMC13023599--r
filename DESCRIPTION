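Package: resphrv
Title: Hilbert Respiratory Decomposition and Continuous Parasympathetic
    Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Relates three representations of spontaneous respiration (the
    band-limited waveform, Hilbert instantaneous amplitude as respiratory
    depth, and sign-inverted Hilbert instantaneous frequency as respiratory
    rate) to continuous parasympathetic heart rate variability indices
    (log high-frequency power, RMSSD, and the Poincare cardiac vagal
    index) computed on a 5 s sliding window. Includes Pan-Tompkins QRS
    detection, physiological R-R gating with cubic-spline repair, monotone
    Hermite tachogram resampling, Lomb-Scargle spectral estimation on
    irregular beat times, within-participant Spearman correlations with
    Fisher z transformation, and repeated-measures ANOVA with
    Bonferroni-corrected pairwise comparisons.  A synthetic
    cardiorespiratory cohort generator (integral pulse frequency
    modulation with configurable coupling of vagal modulation to
    respiratory depth and rate) provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
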