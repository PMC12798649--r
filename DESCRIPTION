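Package: connfit
Title: Predicting Task Activation from Resting-State Connectivity Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits vertex-wise task-activation maps from resting-state
    functional-connectivity fingerprints with per-region ridge regression
    models, assesses each fit against a within-region permutation null, and
    compares fits across cognitive domains, lobes, and hemispheres. Includes
    a calibrated synthetic-data generator (parcellation, multi-run vertex
    timeseries with nuisance compartments, activation maps with planted
    fingerprint-to-activation coupling) so the full pipeline is testable
    without access-controlled neuroimaging data, plus aCompCor-style
    nuisance regression, Fisher-z group connectivity averaging, and a
    group-statistics layer (arcsine-square-root ANOVA with eta-squared,
    Holm-corrected pairwise contrasts, hemispheric laterality tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    RNifti,
    optparse,
    parallel
Config/testthat/edition: 3
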