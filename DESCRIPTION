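Package: atlasquant
Title: Atlas-Based Quantification of Stained Features in Serial Brain Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for atlas-based regional quantification of
    immunohistochemistry in serial brain sections. Slices a labeled 3D
    annotation volume into atlas plates along per-section anchoring planes,
    refines the linear registration with a piecewise-affine anchor-point
    deformation field, scores registration accuracy and section damage by
    systematic random sampling, compiles custom region hierarchies, measures
    per-region stain load (percent stain-positive coverage per region area),
    and integrates regional load with bulk RNA-seq counts via plain and
    age-adjusted (within-group centered) Pearson correlations with false
    discovery rate control and gene categorization. Includes a synthetic-data
    generator (mini-atlas, warped and damaged sections, designed expression
    matrices) so the whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
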