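Package: ldaepr
Title: Loudness Dependence of Auditory Evoked Potentials: Simulation,
    Estimation and Treatment-Response Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the loudness dependence of auditory evoked
    potentials (LDAEP), a putative inverse electrophysiological marker of
    central serotonergic activity.  Simulates multi-channel auditory
    evoked EEG with known ground-truth intensity-dependence slopes,
    preprocesses raw recordings (zero-phase band-pass filtering,
    regression-based ocular correction, epoching, amplitude-based
    artifact rejection, per-intensity averaging), detects N1/P2 peaks at
    the vertex and fits scalp LDAEP slopes by linear regression over
    stimulus intensities, estimates standardized source current density
    with an sLORETA-type inverse on a three-shell spherical head model
    and fits source LDAEP slopes for auditory-cortex regions of interest,
    and stratifies clinical cohorts (responder, remitter, median LDAEP
    split) with the group statistics used in treatment-response studies
    (pooled and Welch t, paired t, chi-square, relative odds, Cohen's d,
    sex-covariate linear models, Kolmogorov-Smirnov normality checks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
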