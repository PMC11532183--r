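Package: fibroquant
Title: Quantification of Liver Fibrosis from Sirius-Red-Stained Biopsy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for quantifying liver fibrosis in
    Sirius-Red (picrosirius) stained biopsy sections. Segments collagen via
    optical-density stain projection, computes the Estimated Collagen Area
    (ECA) and Entropy of Collagen (EnC) at pixel and 32x32-pixel ROI scales
    together with an extended intensity/texture/morphology feature battery,
    renders per-ROI heatmap overlays, and provides the accompanying
    statistical layer: Fleiss kappa inter-rater agreement with
    Landis-Koch-style bands, paired t-tests, one-way ANOVA with Tukey HSD,
    stage-wise summaries, and paired pre-/post-treatment response
    classification from congruous ECA and EnC changes. Includes a synthetic
    slide generator with exact ground-truth masks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
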