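Package: facespace
Title: Data-Driven Trait Dimensions in a Multidimensional Face Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits perceptual trait dimensions (attractiveness, sexual
    dimorphism) as best linear fits of standardized Likert ratings onto
    face coordinates in a 100-dimensional face space, orthogonalizes one
    trait direction against another so faces can be exaggerated along a
    target percept while a nuisance percept is held constant, and
    validates the dissociation with hierarchical Bayesian regressions of
    ratings on exaggeration level (WAIC model selection, generated
    quantities), inter-rater reliability statistics (Cronbach's alpha,
    ICC(2,1)) and Bayesian rank correlations. Includes a synthetic
    face-and-rater generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'faceSpace.R'
    'facespace-package.R'
    'traitModel.R'
    'hierModel.R'
    'syntheticData.R'
    'pipeline.R'
    'reliability.R'
    'utils.R'
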