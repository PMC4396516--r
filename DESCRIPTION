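Package: eegBands
Title: Individually Anchored EEG Frequency Bands and the Alpha3/Alpha2 Risk Biomarker
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Resting-state quantitative EEG analysis with individually anchored
    frequency bands. Detects the theta/alpha transition frequency (TF) and the
    individual alpha frequency (IAF) peak on the channel-averaged ("collapsed")
    Welch spectrum, derives subject-specific delta/theta/alpha1/alpha2/alpha3
    bands, computes relative band powers and the alpha3/alpha2 power ratio, and
    stratifies subjects into low/middle/high risk classes. Companion modules
    provide age-corrected perfusion W-scores for regional cerebral blood flow
    tables, radial morphometry of 3D binary segmentation masks (medial curve
    plus surface-to-curve distances), the cohort-level statistics used with
    these biomarkers (Pearson correlation, Student's t from raw data or summary
    statistics, chi-square, one-way ANOVA with Levene-gated Games-Howell or
    Bonferroni post hocs), and seedable synthetic generators for multichannel
    EEG and cohort tables so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    RNifti,
    car,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
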