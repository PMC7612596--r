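Package: suvrepeat
Title: Test-Retest Repeatability and Interobserver Variation of PET SUV
    Measurements in Healthy Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the test-retest repeatability and
    interobserver variation of standardized uptake value (SUV) measurements
    from FDG-PET volumes of healthy tissue. Converts activity-concentration
    volumes to body-weight SUV, extracts SUVmax, SUVmean and SUVpeak from
    spherical volumes of interest and voxel-mask regions, and implements the
    log-transformed repeatability framework: within-subject coefficient of
    variation, asymmetric repeatability coefficients with chi-square
    confidence intervals, Bland-Altman summaries, bias and trend tests with
    Bonferroni family correction. Includes a synthetic cohort generator and
    digital phantom simulator so the full pipeline can be exercised and
    validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
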