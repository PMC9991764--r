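Package: sodium24
Title: Dietary Sodium Estimation Methods and Their Agreement with 24-h Urinary Sodium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating daily dietary sodium intake from urinary and
    dietary instruments and for comparing those estimates against the reference
    24-h urine collection. Implements the 24-h urinary sodium calculation with
    collection-completeness screening, six published spot-urine conversion
    equations (Kawasaki, Tanaka, INTERSALT with and without potassium, Mage,
    Toft), mean 24-h dietary recall sodium with two discretionary-salt
    corrections (per-meal salt questions; a fixed 15% discretionary share), and
    frequency-weighted FFQ scoring including a sodium-extended FFQ (NaFFQ) with
    cooked-meal salt quantification. A seeded synthetic-cohort generator with a
    known measurement-error structure drives an end-to-end method-comparison
    pipeline reporting bias with paired tests, Pearson and Spearman
    correlations, two-way single-measure intraclass correlation with
    Koo-Li reliability bands, and Bland-Altman limits of agreement with
    proportional-bias regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nortest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
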