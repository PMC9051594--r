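Package: psmarepeat
Title: Test-Retest Repeatability of PSMA PET Whole-Body Tumor Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the test-retest repeatability of
    prostate-specific membrane antigen (PSMA) PET derived tumor burden
    metrics. Implements liver-referenced whole-body lesion segmentation
    (SUVpeak candidate detection with a tumor-sink-corrected liver
    threshold and 50% isocontour delineation), per-lesion and per-patient
    volumetric and uptake metrics (molecular tumor volume, PSMA total
    lesion uptake and quotient), and test-retest statistics: within-subject
    coefficient of variation, repeatability coefficient, bootstrap
    confidence intervals, Bland-Altman agreement, and intraclass
    correlation. Ships a synthetic paired-phantom and paired-cohort
    generator with known ground truth so the whole pipeline is testable
    end to end, plus an 18-patient example test-retest cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
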