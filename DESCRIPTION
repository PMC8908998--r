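Package: fpolcyto
Title: Quantitative Fluorescence Polarization Imaging of Cytology Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for confocal fluorescence polarization (Fpol) cytology:
    converts paired co-/cross-polarized 8-bit image stacks into per-cell Fpol
    values via validity masking, frame averaging and G-factor calibrated
    polarization ratios; renders digitally stained emission images and
    pseudo-colored Fpol maps; aggregates cells to samples and diagnostic
    groups; fits a mixed-effects model comparing malignant, benign and normal
    thyroid groups; and classifies cells and samples against an Fpol
    discrimination threshold. Includes a synthetic cohort and polarized-image
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    png,
    EBImage,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
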