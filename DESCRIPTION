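Package: cectvar
Title: Measurement Variability of Lesion Diameter and Density on Dynamic
    Contrast-Enhanced CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying test-retest variability of hepatocellular
    carcinoma lesion measurements across dynamic contrast-enhanced CT phases.
    Extracts maximal in-plane (Feret) diameters and mean Hounsfield-unit
    densities from segmentation masks, computes per-lesion and pooled
    coefficients of variance with confidence intervals, limits-of-agreement
    ranges, waterfall maxima, size-stratified summaries and size-variability
    correlations, and classifies paired changes against RECIST 1.1, mRECIST
    and modified Choi thresholds. Includes a synthetic dynamic-CECT phantom
    generator with known ground truth so the full pipeline is verifiable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
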