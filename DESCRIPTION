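Package: heartage
Title: Biological Heart Age Estimation from Cardiac Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates biological heart age from tabular cardiac magnetic
    resonance radiomics features. Provides confound residualization,
    a Bayesian ridge regression fitted by iterative evidence (type-II
    maximum likelihood) updates, sex-stratified k-fold cross-validated
    age prediction with regression-dilution bias correction yielding a
    heart-age delta, Pearson profiling of feature-age associations with
    Bonferroni control, and a category-wise-Bonferroni phenome-wide
    association study of exposures against the delta. Includes a
    synthetic cohort generator with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
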