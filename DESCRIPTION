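Package: wingshape
Title: Landmark-Based Geometric Morphometrics for Taxonomic Assignment of
    Insect Wings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for landmark-based geometric morphometrics of insect
    forewings aimed at taxonomic placement of unknown specimens such as
    compression fossils. Reads and writes the TPS landmark format, performs
    generalized least-squares Procrustes superimposition with tangent-space
    projection and an adequacy check of the linear approximation to Kendall
    shape space, fits rank-safe linear discriminant models on shape
    coordinates with leave-one-out cross-validation, and assigns unknown
    configurations to reference groups by Mahalanobis distance and posterior
    probability, with replicate-digitization consensus reporting. A seeded
    synthetic-wing generator reproduces the statistical structure the
    analysis assumes (group-distinct mean shapes, isotropic landmark noise,
    similarity-transform nuisance, digitization error) so the whole pipeline
    is testable without access to original specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
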