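Package: bioage
Title: Biological Age Estimation from Physiological Biomarkers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates biological age from panels of physiological biomarkers
    using the first principal component of the standardized biomarker matrix.
    Provides systematic biomarker screening (age-correlation gating and
    redundancy pruning), conversion of the principal-component score to years
    via the T-scale method, correction for regression toward the mean,
    agreement diagnostics (regression against chronological age, standard
    error of the estimate, paired t test, Bland-Altman limits of agreement),
    a synthetic-cohort generator for testing the full pipeline, and a
    command-line interface covering simulation through evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
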