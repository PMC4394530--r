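---
title: "Loudness dependence of auditory evoked potentials: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loudness dependence of auditory evoked potentials: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldaepr)
```

## The biomarker and the estimator

The loudness dependence of auditory evoked potentials (LDAEP) quantifies
how strongly the auditory cortex response grows with stimulus intensity.
Tones at five intensities (55, 65, 75, 85, 95 dB SPL) evoke an N1
deflection (most negative point 80--130 ms after the tone) and a P2
deflection (most positive point 130--230 ms) at the vertex electrode Cz.
For each intensity $I$ the peak amplitudes $A_{N1}(I)$, $A_{P2}(I)$ and
the peak-to-peak difference $A_{N1/P2}(I) = A_{P2}(I) - A_{N1}(I)$ are
measured on the per-intensity averaged waveform, and the LDAEP is the
ordinary least-squares slope

$$\widehat\beta = \frac{\sum_I (I - \bar I)(A(I) - \bar A)}{\sum_I (I - \bar I)^2}
\quad [\mu V / dB].$$

`ldaep()` is the package's core fitting function; it returns a classed
model object with `coef`, `predict`, `summary`, `plot`, `residuals` and
`simulate` methods.  Because least squares is linear in the response,
the N1/P2 slope equals the P2 slope minus the N1 slope identically --
a property the test suite asserts per subject and that also holds, to
printed rounding, in the published group means the package ships as
fixtures.  The N1 slope is computed on the *signed* N1 amplitude, so
typical N1 slopes are negative.  Slopes are invariant to centering the
intensity axis and to constant amplitude offsets; regression uses the
raw dB values and exactly five points (the per-intensity averages, not
single trials).

LDAEP is of clinical interest as a putative inverse marker of central
serotonergic tone: cohorts treated with selective serotonin reuptake
inhibitors show better treatment response in patients with a *high*
pretreatment N1/P2 LDAEP.  The `cohort_stats` layer of this package
reproduces that analysis: responder stratification (strict >50% BDI
reduction), remission (post-treatment BDI strictly below 10), a median
split on the pretreatment N1/P2 slope, and the group statistics used in
such studies (pooled and Welch t, paired t, Pearson chi-square without
continuity correction, group-vs-total relative odds, Cohen's d,
sex-adjusted linear models, Kolmogorov--Smirnov normality checks).

## Preprocessing model

Raw recordings are processed in a fixed, deterministic order:

1. **Band-pass 1--30 Hz, zero phase.**  Realized as a 2nd-order
   Butterworth high-pass cascaded with a 4th-order low-pass, each
   applied forward-backward (`signal::filtfilt`).  The cascade keeps
   the 1 Hz edge numerically well conditioned at a 1000 Hz sampling
   rate; zero-phase filtering leaves symmetric peak latencies unchanged
   (tested to within one sample).
2. **Ocular correction.**  Per-channel regression of the EEG on the
   EOG channels over blink segments (samples where the vertical EOG
   exceeds 40 uV), with the fitted EOG contribution subtracted over the
   whole recording.  A recording with flat EOG passes through
   unchanged.  This is a standard regression-based blink correction;
   the package makes no attempt to replicate any proprietary
   implementation.
3. **Reference.**  Linked mastoids (M1/M2 average) by default for scalp
   analysis, switchable to common average.  The reference is a
   documented assumption, recorded in provenance: mastoids are recorded
   but excluded from source analysis, which makes the linked-mastoid
   choice natural, not inevitable.
4. **Epoching.**  Window -100 to +400 ms around each tone (inclusive
   millisecond bounds; 0 ms = onset), baseline -100 to 0 ms subtracted
   per channel.  Events too close to the recording edge are flagged
   rejected with reason `"edge"`, never silently dropped.
5. **Artifact rejection.**  An epoch is rejected when any EEG channel
   exceeds 70 uV in absolute amplitude anywhere in the window.  The
   70 uV threshold is configurable; rejection rates are recorded per
   intensity and a warning is emitted at 5% or more.  Rejecting every
   epoch of an intensity is a hard error because averaging would be
   impossible.  Whether correction precedes rejection is not a settled
   convention; this package corrects first, then rejects.
6. **Averaging** retained epochs per intensity (arithmetic mean).

## Source analysis

Source LDAEP uses a standardized minimum-norm inverse of the sLORETA
family.  With lead field $L$ (average-referenced, mastoids excluded),
regularization $\alpha$ and average-reference projector $H$, the
minimum-norm kernel is $T = L^\top (L L^\top + \alpha H)^{+}$ and the
standardized power of source $i$ for sensor data $v$ is

$$\hat p_i = \frac{[(Tv)_i]^2}{[T L]_{ii}}$$

(for free orientations, the quadratic form with the inverse of the
3x3 diagonal block).  Standardization by the resolution-matrix diagonal
gives the defining property of sLORETA: a noiseless field generated by
any single grid source is localized to exactly that source.  The test
suite verifies this exhaustively on a small grid, verifies quadratic
scaling in the data, invariance to re-referencing, and cancellation of
a global lead-field gain when forward simulation and inverse use the
same model.

The head model is a deliberate reduction: a three-shell concentric
sphere (brain/skull/scalp radii 0.087/0.092/0.100 m, conductivities
0.33/0.0042/0.33 S/m) with a quasi-uniform Fibonacci grid of radially
oriented sources (default 254) at 0.078 m, and an idealized spherical
10-10 montage constructed geometrically (64 EEG + 4 EOG channels).
The forward solution is the analytic spherical-harmonics series; the
per-degree boundary factors are obtained by solving the interface
conditions numerically (with column equilibration for high degrees),
which reduces exactly to the classical homogeneous-sphere factor
$(2n+1)/n$ when all conductivities are equal -- an identity the tests
assert.  A realistic MRI-based volume conductor with thousands of
voxels and anatomical labelling is out of scope; the estimator
mathematics is identical on the reduced model and that is what the
package is meant to validate.

The auditory-cortex region of interest is a pair of lateral-temporal
caps (25 degrees angular radius) around mirrored left/right directions.
Standardized density is averaged over each ROI and over three windows:
the N1 window (80--130 ms), the P2 window (130--230 ms) and a broad
60--240 ms window.  Published source-LDAEP work reports N1, P2 and
N1/P2 source slopes while describing a single broad average; because
the mapping between the two descriptions is not documented anywhere,
this package computes and labels all three windows explicitly and
leaves the choice to the analyst.  Slopes are fitted per window for
the left ROI, the right ROI, and the mean of the two hemisphere
series.  The regularization default is
$\alpha = \mathrm{tr}(LL^\top)/(m\,\mathrm{SNR}^2)$ with SNR 10;
no published value exists for this analysis, so it is exposed as a
parameter.

## What the simulator emulates

`simulate_subject_eeg()` generates multichannel raw EEG in which every
quantity the pipeline later estimates is known exactly:

- **Evoked components.**  Gaussian-windowed deflections (sigma 15 ms,
  compact support of 5 sigma) at configurable latencies (defaults 100
  and 180 ms, on-grid at the supported sampling rates).  Vertex
  amplitudes follow `baseline + slope x (intensity - 75)`.  The scalp
  topography is the projection of a bilateral superior-temporal source
  pair through the package's own forward model, rescaled so the
  linked-mastoid-referenced Cz amplitude equals the nominal amplitude
  exactly -- this is what makes noiseless end-to-end recovery exact to
  machine precision rather than approximate, and it means the same
  dataset exercises the inverse coherently.
- **Stimulus timing.**  1 kHz tones, 80 ms duration, with the
  inter-stimulus interval read as the offset-to-onset gap, drawn
  uniformly from 500--900 ms (the standard ERP usage); successive
  onsets are therefore 580--980 ms apart.  Intensity labels are
  exactly balanced and shuffled by the seed.
- **Background activity.**  Independent per-channel 1/f noise with an
  alpha (10 Hz) spectral peak, scaled to a configurable standard
  deviation (default 4 uV).
- **Blinks** at a configurable rate on the EOG channels, propagated to
  EEG channels with geometrically decaying factors (overridable, so
  tests can inject a known propagation).
- **Artifact epochs.**  A configured fraction of events receives a
  90--150 uV transient on one random channel, which the 70 uV rule
  must catch; the injected fraction is the ground truth for the
  measured rejection rate.

Deliberately *not* emulated: spatially correlated noise, drifting
electrode impedances, channel dropout, medication effects over time,
and any longitudinal change in the LDAEP.  Passing tests therefore
show estimator correctness under a controlled, additive model -- not
robustness to every pathology of clinical EEG.

The evoked amplitudes default to a scale (N1 -10 uV, P2 +15 uV at
75 dB) consistent with published slope magnitudes in uV/dB over a
40 dB range; with large slopes the low-intensity P2 can approach zero,
which reproduces the floor effects real low-intensity AEPs show.

## Cohort generator and its calibration

`generate_cohort()` draws a clinical table whose group structure
mirrors the reference cohort: 41 subjects (7 male), 15 first-episode,
10 smokers, 21 on hypnotics, antidepressant assignment as metadata,
and a low/high LDAEP group split of 20/21.

Two calibration choices deserve explanation:

- **Joint N1/P2 slopes.**  Group summaries specify means and SDs for
  N1, P2 *and* their difference N1/P2.  Drawing N1 and P2
  independently would inflate the N1/P2 SD, so the generator draws
  them bivariate-normally with the correlation implied by the three
  SDs, $\rho = (s_{N1}^2 + s_{P2}^2 - s_{N1/P2}^2)/(2 s_{N1} s_{P2})$;
  all three configured moments are then matched simultaneously.
- **Percent BDI reduction.**  Reduction is truncated to [-50, 100]
  (values above 100 are impossible; the lower bound prevents absurd
  worsening).  A single truncated normal cannot have mean 70.2 and SD
  36.2 on that interval -- the distribution must be left-skewed with
  mass piled near the 100% ceiling, which is also what real responder
  data look like (near-complete remissions coexist with partial and
  non-response).  The generator therefore uses a two-component mixture
  of truncated normals: a narrow "near-complete remission" component
  at 95% and a broad partial-response component, with the mixture
  weight and broad-component parameters moment-matched (analytic
  truncated moments, numerical optimization) so the mixture has
  exactly the configured mean and SD.  The calibration is exact for
  both default groups and is verified empirically at n = 4000 within
  three standard errors.

`bdi_post` is derived as `round(bdi_pre * (1 - reduction/100))`
clipped at zero, because the BDI is an integer scale.  Demographics
are assigned independently of LDAEP group; the generator makes no
attempt to reproduce secondary demographic-by-group associations.

## Numerical and design notes

- The "70 mV" rejection threshold that appears in some printed methods
  text is treated as a typographical slip for 70 uV; a 70 mV scalp EEG
  amplitude is physiologically impossible.
- Peak windows use inclusive endpoints; amplitude ties break toward
  the earliest latency; flat search windows are flagged, not errors.
- The two-sample t supports pooled and Welch modes plus an `"auto"`
  mode that switches to Welch when an F test of variance equality
  rejects at 0.05 -- published tables mix integer and fractional
  degrees of freedom exactly as such a rule would produce.
- The group-vs-total relative odds (odds of the event in one group
  divided by the odds in the whole sample) is the definition that
  reproduces published values of 1.91 and 0.49 from the responder
  counts; the conventional cross-product odds ratio of the same table
  is 3.91 and is always reported alongside, clearly labelled.
- Chi-square is Pearson's statistic without continuity correction --
  with Yates correction the published 4.188 is not reproducible.
- Cohen's d from the shipped BDI-change summaries is 0.856; published
  rounding reports 0.8.  Both are consistent with the same underlying
  contrast; the package computes, never hard-codes, the value.
- The Kolmogorov--Smirnov check is reported only; it never switches
  methods silently.
- No multiple-testing adjustment is applied anywhere, matching the
  analysis the package reproduces; reports carry the count of tests
  performed so readers can judge.
- EDF export pads recordings to whole seconds (one-second records) and
  scales each channel to the 16-bit range of its amplitude maximum;
  round-trip error is bounded by one quantization step.
- Every pipeline output directory is keyed by an MD5 hash of the
  resolved configuration, so runs with different settings never share
  files silently.

## Problem sizes

The test suite and the acceptance script favour small, fast problem
instances chosen to make each property decisive: 25--250 simulated
tones per subject at 250--500 Hz for recovery and rejection
properties, 12-subject cohorts for estimator-fidelity correlations,
50--60-source grids for exhaustive localization checks, n = 4000
cohorts for generator calibration, and 1000-replicate null
simulations for the GLM's type-I error.  The estimators themselves are
size-agnostic; the full 1000-tone, 1000 Hz, 254-source configuration
is the package default for real use.

## Limitations

Scalp results validate against ground truth exactly; source results
validate structural properties (localization, lateralization, sign of
intensity dependence) rather than absolute density values, which have
no physical calibration on a reduced spherical model.  The simulator's
noise model is additive and channel-independent, so sensor-space SNR
is optimistic relative to clinical data.  Cohort-level conclusions
drawn from simulated cohorts inherit the generator's assumptions
(normal LDAEP groups, mixture-calibrated response coupling) and cannot
stand in for new clinical evidence.
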