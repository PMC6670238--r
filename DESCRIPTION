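Package: RGCount
Title: Semi-Automated Retinal Ganglion Cell Counting in Flat-Mount Retinas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Size-segmentation counting of fluorescently labeled retinal
    ganglion cell somata in flat-mounted retinas. Provides reading and
    maximum-intensity projection of calibrated TIFF mosaics, the
    four-quadrant by three-eccentricity (central/middle/peripheral)
    twelve-segment sampling scheme, a detector that filters, thresholds
    (Otsu or user-defined), binarizes, labels connected components,
    excludes noise by size and splits overlapping-cell clusters by the
    rounded ratio of object area to mean single-cell area, conversion of
    counts to densities (cells per square millimetre) with per-retina
    aggregation, the associated group statistics (t test, one-way ANOVA
    with Tukey HSD, Spearman rank correlation with behavior score,
    automated-versus-manual agreement), and a calibrated synthetic image
    generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'RGCount-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'cli.R'
    'density-stats.R'
    'detector.R'
    'geometry.R'
    'imaging-io.R'
    'synthetic.R'
    'utils.R'
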