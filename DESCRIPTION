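Package: foldquant
Title: Quantification of Epithelial Fold Boundaries in Imaginal Discs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microscopy-derived measurements of
    epithelial fold boundaries in the Drosophila eye-antenna disc:
    classification of per-cell apical-area dynamics (constant, fluctuating,
    constricting), background-normalized expression-profile quantification
    and co-expression calling across a sharpening gene-expression border,
    clone scoring against a fold polyline for lineage-restriction analysis,
    contour-stack cell volumetry, and cell-trajectory fold-crossing
    detection. Includes a seeded synthetic-data generator emulating the
    statistical structure of segmentation and intensity tables so the whole
    pipeline is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    mgcv,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
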