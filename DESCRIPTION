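Package: fwtrace
Title: Free-Water White-Matter Microstructure and Cognitive Decline Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying white-matter microstructure and cognition in
    aging cohorts: per-voxel single-shell bi-tensor free-water fitting with
    free-water-corrected tensor scalars, tract-level feature extraction with
    age-regressed outlier exclusion, longitudinal ComBat harmonization of
    imaging batch effects, cross-sectional and longitudinal mixed-effects
    association scans with false-discovery-rate control, bootstrapped marginal
    R-squared head-to-head comparisons, and endophenotype interaction models.
    Includes a multi-cohort longitudinal study simulator with known ground
    truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    car,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
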