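Package: volcurve
Title: Biomarker-Stratified Nonparametric Brain Age-Volume Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how preclinical Alzheimer's and vascular
    biomarkers alter cross-sectional age-volume associations in cognitively
    normal adults. Implements CSF/vascular A/T/N/V stratification of a cohort
    into biomarker groups, intracranial-volume normalization and z-scoring of
    regional brain volumes, Nadaraya-Watson kernel regression "volume curves"
    with bootstrap uncertainty bands and cross-validated bandwidth selection,
    and curve comparison via the area between curves with a chi-squared
    significance test and Bonferroni correction. A synthetic-cohort generator
    with known ground-truth trajectories makes every stage testable without
    access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
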