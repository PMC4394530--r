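# ldaepr

Scalp and source analysis of the **loudness dependence of auditory
evoked potentials (LDAEP)** — a putative inverse electrophysiological
marker of central serotonergic activity — together with the cohort
statistics that link pretreatment LDAEP to SSRI treatment response in
major depressive disorder.

The package is written for EEG/ERP methodologists and biostatisticians
who want a fully testable version of this analysis: because raw
clinical EEG for such studies is generally unavailable, it ships a
synthetic-data layer that generates multichannel auditory-evoked EEG
and clinical cohorts with *known* ground truth, so every estimator can
be validated end to end.

## The model

Tones at five intensities (55, 65, 75, 85, 95 dB SPL) evoke the N1
(most negative deflection 80–130 ms post-stimulus) and P2 (most
positive, 130–230 ms) components at the vertex (Cz). With A(I) the
peak amplitude at intensity I (N1, P2, or the peak-to-peak difference
N1/P2 = P2 − N1), the LDAEP is the least-squares slope

    LDAEP = Σ (I − Ī)(A(I) − Ā) / Σ (I − Ī)²   [µV/dB]

fitted over the five per-intensity averaged responses. By linearity,
slope(N1/P2) = slope(P2) − slope(N1) identically.

Source LDAEP applies the same regression to standardized current
density from an sLORETA-type inverse, T = Lᵀ(LLᵀ + αH)⁺, with power
standardized by the resolution-matrix diagonal — the construction with
zero localization error for noiseless point sources — averaged over
left/right auditory-cortex ROIs on a three-shell spherical head model.

The cohort layer stratifies subjects (responder: >50% BDI reduction;
remitter: post-treatment BDI < 10; low/high LDAEP by median split) and
computes pooled/Welch/paired t statistics, Pearson χ² (no continuity
correction), group-vs-total relative odds, Cohen's d, sex-adjusted
linear models and Kolmogorov–Smirnov normality checks.

## Worked example

Re-analysis of published group summaries (shipped as plain-text
fixtures under `inst/extdata/`):

```r
library(ldaepr)
ref <- reference_cohort_tables()
g <- function(v, grp) reference_group(ref$summaries, "response", v, grp)

two_sample_t(g("pre_p2", "nonresponder"), g("pre_p2", "responder"),
             mode = "welch")
#> t_welch = -2.499, df = 36.984, p = 0.017
#>  group  n mean   sd
#>      a 16 0.58 0.40
#>      b 25 1.06 0.82

chi_square_2x2(as.matrix(ref$counts[, c("responders", "nonresponders")]))
#> chi2 = 4.188, df = 1, p = 0.0407
```

Responders have a higher pretreatment P2 LDAEP than nonresponders
(Welch t on the printed summaries), and responder status is associated
with the high-LDAEP group (χ² on the printed counts).

Simulation with known ground truth, recovered by the full pipeline:

```r
fit <- ldaep(c(2.0, 2.5, 3.5, 4.0, 5.0), component = "N1/P2")
fit
#> N1/P2 LDAEP: slope 0.075 per dB (intercept -2.225, R^2 0.987)

seq <- generate_stimulus_sequence(40, seed = 1)
truth <- ground_truth(slope_n1 = -0.45, slope_p2 = 0.95)
raw <- simulate_subject_eeg(seq, truth, seed = 2, srate = 500)
raw
#> EEG recording: 68 channels x 16500 samples @ 500 Hz (33.0 s), 40 events, reference: none

evoked <- preprocess_recording(raw, pipeline_config(srate = 500, n_events = 40))
compute_scalp_ldaep(evoked)
#> Scalp LDAEP at Cz (uV/dB):
#>      n1      p2    n1p2
#> -0.4503  0.7898  1.2401
```

The estimated slopes (−0.45, 0.79, 1.24 µV/dB) recover the injected
ground truth (−0.45, 0.95, 1.40) up to averaging noise at 8 epochs per
intensity; with noise disabled the recovery is exact to machine
precision. `run_pipeline()` chains the same stages over a whole
simulated cohort, adds the source-space slopes, and writes the LDAEP
table, comparison tables and provenance to a hash-keyed output bundle.

See the vignette (`vignettes/ldaep-methods.Rmd`) for the model
assumptions, the head-model reduction, and the calibration of the
cohort generator.

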