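Package: eegdx
Title: EEG Biomarker Batteries and Integrative Diagnostic Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting conversion from mild cognitive impairment
    to Alzheimer's disease from eyes-closed resting-state EEG. Extracts a
    large per-channel battery of spectral, temporal and spatial biomarkers
    (1/f-corrected spectral peak fits, detrended fluctuation analysis,
    multifractal spectral width, oscillation-burst and phase-burst
    statistics, Hjorth, Barlow and Wackermann parameters, amplitude-envelope
    statistics and correlations), maps group differences channel-wise with a
    binomial multiple-comparison correction, and integrates selected
    biomarkers into a logistic diagnostic index by genetic search or
    elastic-net penalized regression. Includes a synthetic EEG cohort
    generator with controllable 1/f background, oscillation peaks and
    long-range temporal correlations, outcome evaluation (sensitivity,
    specificity, positive predictive value, positive likelihood ratio,
    Matthews correlation) with Monte-Carlo significance thresholds, and a
    reproducible end-to-end pipeline with train/test visit separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    boot,
    glmnet,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
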