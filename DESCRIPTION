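Package: lunghist
Title: Histogram Analysis of Hounsfield Units in Unenhanced Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative histogram analysis of Hounsfield-unit (HU)
    distributions inside lung-lesion regions of interest on unenhanced
    chest CT. Computes per-slice first-order ROI statistics (mean,
    minimum, maximum, standard deviation), per-group histograms and
    normalized cumulative distributions with crossing detection,
    per-HU-bin class-conditional probabilities with dominance-region
    derivation, and threshold-rule classification of lesions as
    malignant-consistent or benign-suggestive. Includes a synthetic
    two-group cohort and phantom generator so the full pipeline is
    testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    graphics,
    jsonlite,
    rlang,
    RNifti,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
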