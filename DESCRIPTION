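Package: ccsrt
Title: Retention Time and Collision Cross-Section Prediction for Metabolite Annotation Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains quantitative structure-retention relationship (QSRR) and
    cluster-based collision cross-section (CCS) regression models from a
    library of metabolite standards measured by ion-mobility LC-HRMS,
    calibrates prediction-error tolerance windows (MAE + 2 SD), builds a
    predicted metabolite/adduct annotation database, and filters untargeted
    feature annotations by combined m/z, CCS and retention-time matching to
    remove false-positive identifications. Includes a synthetic-data
    generator with known ground truth for end-to-end evaluation of the
    annotation filter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    cluster,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
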