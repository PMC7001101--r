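Package: cervitex
Title: Endovaginal MRI Radiomics for Cervical Tumour Texture and Recurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Masked grey-level co-occurrence matrix (GLCM) texture analysis of
    T2-weighted volumes and apparent diffusion coefficient (ADC) maps of
    cervical tumours, with feature de-correlation by hierarchical clustering,
    volume-dichotomized nonparametric group comparison, and recurrence
    prediction by stepwise logistic regression validated through bootstrap
    optimism correction on Somers' D. Includes a synthetic phantom and cohort
    generator so the full pipeline is testable without patient data, a
    mono-exponential ADC fitter for multi-b-value diffusion series, and
    NIfTI/CSV interfaces for volumes, masks and feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
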