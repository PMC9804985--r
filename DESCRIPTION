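Package: isletquant
Title: Quantification of Pancreatic Islet Composition from Immunofluorescence and Brightfield Immunostaining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments pancreatic islets from multichannel immunofluorescence
    images (nuclear counterstain, synaptophysin, insulin) and from
    colour-deconvolved brightfield immunohistochemistry tiles, and quantifies
    the islet microenvironment: islet area as a fraction of tissue area,
    insulin-positive fraction of islet area, and insulin signal integrated
    within synaptophysin-delineated islet masks. Per-animal read-outs are
    compared between groups with the study workflow of log10 transformation,
    Bartlett and Shapiro-Wilk assumption checks, and two-sided Dunnett
    many-to-one tests. A synthetic-cohort generator with known ground truth
    supports end-to-end validation and statistical calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
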