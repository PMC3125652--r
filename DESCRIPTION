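Package: basalmorph
Title: Basal Cell Layer Morphometry from Labeled Microscopy Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometry of the basal cell layer of oral
    epithelium. Measures cell and nuclear area and perimeter in calibrated
    physical units from integer-labeled mask images via sub-pixel
    iso-contours, computes the classical shape descriptors (form perimeter,
    contour index) and the nuclear-cytoplasmic ratio, and runs the group
    comparison statistics used in diagnostic morphometry studies (one-way
    ANOVA, pooled two-sample t, Mann-Whitney U with tie-corrected normal
    approximation, Kruskal-Wallis). Includes a seeded synthetic-histology
    generator producing label-mask fields and tabular measurement datasets
    with group structure matching a packaged reference dataset of normal
    buccal mucosa, leukoplakia and well-differentiated squamous cell
    carcinoma cases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    tiff,
    png,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
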