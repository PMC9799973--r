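Package: cortexQuant
Title: Quantification of Cortical Fluorescence Asymmetry in Early Embryos
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify cortical fluorescence in single-cell embryo
    time-lapse movies: embryo segmentation, sub-pixel cortex contour
    extraction anchored at the anterior pole, contour straightening with
    perpendicular maximum-intensity sampling, the cytoplasm-normalized
    cortical accumulation statistic, anterior:posterior asymmetry time
    series, a spline-smoothed boundary-length statistic for the depleted
    posterior domain, cleavage-furrow ingression kinetics, FRAP
    single-exponential recovery fitting, and centrosome-to-cortex distance
    measures. Includes a synthetic-embryo image generator with known ground
    truth so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    mgcv,
    minpack.lm,
    tiff,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CellBiology, Microscopy, Segmentation, TimeCourse, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'utils-geometry.R'
    'accumulation.R'
    'boundary.R'
    'cortexQuant-package.R'
    'frap.R'
    'kinetics.R'
    'straighten.R'
    'segmentation.R'
    'synthetic.R'
    'pipeline.R'
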