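Package: ctdosim
Title: Patient-Size-Adjusted CT Dosimetry and Cohort Dose Auditing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for patient-size-adjusted computed-tomography dosimetry.
    Computes per-study effective diameter from chest AP/LAT dimensions, the
    AAPM Report 204 size conversion factor k, the size-specific dose estimate
    (SSDE = CTDIvol * k), a size-specific dose-length product
    (DLPss = DLP * k), and effective dose (ED = DLP * f). Includes a
    scan-length over-ranging audit, a cohort statistics layer (normality-gated
    two-group tests, Spearman correlation, stratified summaries), and a
    calibrated synthetic-cohort generator so every pipeline stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
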