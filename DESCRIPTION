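Package: choroquant
Title: Volumetric Choroidal Vascularity Quantification from Radial SS-OCT Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies choroidal vascularity from radial swept-source OCT
    B-scan sets. Detects the retinal pigment epithelium, flattens B-scans,
    delineates the choroid by dynamic-programming boundary search, partitions
    it into luminal and stromal compartments with Niblack local thresholding,
    and integrates magnification-corrected luminal, stromal and total
    choroidal volumes and the choroidal vascularity index (CVI) over macular
    rings (0-3, 3-6, 0-6 mm). Includes a synthetic radial-scan phantom
    generator with full ground truth, and paired-design statistics for
    dark/light adaptation studies under physiological challenge
    (covariate-adjusted paired differences and within-condition paired tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
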