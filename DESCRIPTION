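Package: qspkr
Title: Genetic-Algorithm Descriptor Selection and Neural-Network
    Quantitative Structure-Pharmacokinetic Relationship Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-pharmacokinetic relationship
    (QSPkR) models that predict pharmacokinetic parameters (systemic
    clearance, volume of distribution, plasma protein binding) from large
    molecular-descriptor matrices.  A genetic algorithm with an
    award/penalty pairwise fitness function selects a small descriptor
    subset (at most 15 by default) from a min-max normalized descriptor
    table; a three-layer feed-forward neural network trained by
    Levenberg-Marquardt least squares maps the selected descriptors to
    the pharmacokinetic parameter.  Models are assessed by repeated
    random sub-sampling validation with R, RMSE and NRMSE on the
    original measurement scale, plus Levene and t-test checks of split
    homogeneity.  Includes a synthetic-data generator with planted
    informative descriptors for benchmarking, and a command-line
    pipeline with seeded, byte-reproducible artifacts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
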