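Package: synapsight
Title: Interpretable Profiling of Immunological Synapses from Imaging Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature engineering, ensemble feature pre-selection, explainable
    classification, rule-based data cleaning, population-level statistical
    profiling and functional-readout regression for multichannel imaging flow
    cytometry (IFC) records of T cell/B cell conjugates. Images are described by
    interpretable morphology, intensity, texture (GLCM), co-localization and
    synaptic-enrichment features; gradient-boosted trees classify conjugate
    configurations; class-frequency log2 fold changes and per-donor feature
    difference maps summarize antibody effects; percentile-aggregated synapse
    features predict a per-donor functional readout with sparse linear
    regression. A synthetic conjugate-image generator with planted class
    frequencies, feature shifts and a linear functional model makes the whole
    pipeline testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    rhdf5,
    EBImage,
    FNN,
    RANN,
    kernlab,
    glmnet,
    randomForest,
    e1071,
    nnet,
    MASS,
    xgboost,
    uwot,
    igraph,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
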