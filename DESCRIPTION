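Package: vascupet
Title: Blood-Pool PET Quantification of Organ Vascularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for blood-pool PET imaging of organ
    vascularity with tracer-labeled erythrocytes. Provides standardized
    uptake value (SUV) conversion with decay correction, volume-of-interest
    activity totals and histograms, rigid co-registration and clipped
    stress-rest difference imaging with a vasodilation "increased ratio"
    statistic, myocardial infarct sizing from PET slices by three-class
    Otsu stratification and from tetrazolium (TTC) stain photographs by
    color thresholding, exact small-sample Wilcoxon rank tests, and a
    synthetic gated-PET phantom generator with known ground truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
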