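Package: qsarpipe
Title: Curation, Descriptors and Cost-Sensitive Classification for
    Putative Transporter-Substrate QSAR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for binary QSAR
    classification of putative ABCC2 (MRP2) transporter substrates from
    2D chemical structure.  Implements a multistep structure-curation
    protocol (inorganics, mixtures, organometallics, unsupported
    elements, chemotype normalization, duplicates, permanent charges,
    optional protonation of strong acids and bases), a native 2D
    descriptor engine (PEOE partial-charge surface-area bins,
    Wildman-Crippen logP/MR surface-area bins, topological polar
    surface area, hydrogen-bonding and count descriptors), MACCS-key
    and descriptor-space MaxMin diversity splitting, correlation-based
    feature selection with best-first search, cost-sensitive learning
    for imbalanced classes with bagging, imbalance-aware performance
    statistics, PCA applicability-domain checking, and a synthetic
    compound-library generator with a known generative signal for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    e1071,
    rpart,
    ranger,
    class,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
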