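Package: polygcn
Title: Graph Convolutional Prediction of Polymer Nanoparticle Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the hydrodynamic diameter of polymer nanoparticles
    obtained by nanoprecipitation from nothing but the repeat-unit structure,
    the degree of polymerization, and the formulation parameters. A polymer is
    represented as a cyclic ("pseudo-infinite") molecular graph of its repeat
    unit, convolved by a graph convolutional network whose pooled fingerprint
    is fused with the numeric formulation inputs in a fully connected
    regressor trained with a relative (MAPE) loss. Includes replicate-aware
    cleaning of dynamic light scattering measurement tables, seeded training
    with leave-one-polymer-out evaluation, worst-group error decomposition,
    prediction-surface export, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
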