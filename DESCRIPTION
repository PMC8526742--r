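Package: ablaquant
Title: Quantification of Ethanol Ablation Extent from CT and Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying chemical (ethanol and ethyl
    cellulose-ethanol) ablations in tissue. Converts CT radiodensity
    (Hounsfield units) to estimated ethanol concentration with a two-point
    linear calibration, segments the cytotoxic (>= 20 percent) distribution
    volume, computes a radius-of-gyration aspect ratio, cumulative volume
    histograms and maximum concentration projections, performs semi-automated
    necrotic-area segmentation of viability-stained serial sections with
    necrotic volume reconstruction, and correlates the radiologic distribution
    volume with the pathologic ablation zone. Includes seeded synthetic
    phantom and slide-series generators with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    tools,
    utils,
    EBImage,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    png,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ablaquant-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'calibration.R'
    'ct_volumetrics.R'
    'histology.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
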