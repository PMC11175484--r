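Package: wpeniche
Title: Landscape Classification and Maximum-Entropy Niche Modelling of
    Woody Plant Encroachment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-scale analysis of evergreen woody-plant
    distributions and woody plant encroachment (WPE) into grasslands.
    Implements rule-based classification of forest and evergreen forest
    from L-band radar backscatter (HH, HV) and optical vegetation-index
    (NDVI) layers, a two-date change overlay defining encroachment
    pixels, derivation of terrain and distance predictors (slope,
    aspect, ruggedness, Euclidean distance rasters), a from-scratch
    presence-background maximum-entropy niche model with linear,
    quadratic, product, threshold and hinge features and L1-penalised
    fitting, candidate-model grids with ordered three-stage selection
    (partial ROC significance, omission rate, AICc), and range-truncated
    model transfer to independent regions with final partial-ROC
    evaluation. A seeded synthetic-landscape generator provides terrain,
    streams, cover truth and sensor bands so the full pipeline runs and
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
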