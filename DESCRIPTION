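Package: nlcoptim
Title: Design, Neural Surrogate Modeling and Multi-Response Optimization of
    Nanostructured Lipid Carrier Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for optimizing plant-extract-loaded
    nanostructured lipid carrier (NLC) formulations: central composite
    rotatable designs (CCRD) with coded/actual factor transforms, a
    feed-forward TanH neural-network surrogate trained with K-fold
    cross-validation, Garson and permutation variable importance,
    Derringer-Suich desirability multi-response optimization, drug-release
    kinetics model fitting (zero-order, first-order, Higuchi,
    Hixson-Crowell, Korsmeyer-Peppas), entrapment-efficiency arithmetic and
    HET-CAM irritation scoring, plus seeded synthetic-data generators for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
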