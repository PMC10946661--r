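Package: grainPigment
Title: Classification of Barley Grain Pigment Composition from Dish Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for determining the seed-coat pigment composition
    (anthocyanins and/or melanin) of barley accessions from RGB photographs
    of grains in a Petri dish. Implements grain-region semantic segmentation
    with a compact encoder-decoder network, a 2,380-dimensional multi-colour-
    space descriptor scheme with rank-correlation feature filtering, and four
    classification models (colour-descriptor random forest on 13 principal
    components, a residual convolutional classifier, a multi-task
    segmentation network with a classification head, and a two-channel
    per-pixel pigment segmenter with an any-pixel decision rule), together
    with the pooled binary-decision accuracy protocol, confusion matrices and
    hulled-versus-hulless rank-sum comparisons. A synthetic dish-image
    generator with exact ground-truth masks makes every stage trainable and
    testable without photographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    png,
    jsonlite,
    yaml,
    randomForest,
    EBImage,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Segmentation, Phenotyping
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'RcppExports.R'
    'nn-core.R'
    'nn-unet.R'
    'segmentation.R'
    'imageio.R'
    'labels.R'
    'manifest.R'
    'features.R'
    'filter.R'
    'classifiers.R'
    'evaluation.R'
    'grainPigment-package.R'
    'labelme.R'
    'nn-resnet.R'
    'pipeline.R'
    'split.R'
    'synthetic.R'
    'utils.R'
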