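Package: bbbqsar
Title: QSAR Modeling of Blood-Brain Barrier Permeability (logBB)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and applying quantitative structure-activity
    relationship (QSAR) models of blood-brain barrier permeability expressed as
    logBB (log10 brain/blood concentration ratio). Curates SMILES datasets by
    Morgan-fingerprint Tanimoto similarity, computes 2D molecular descriptors,
    removes redundant features by Pearson-correlation filtering with a
    target-relevance keep rule, benchmarks eight regression learners under
    k-fold cross-validation with grid search, and predicts and classifies the
    permeability of query compounds at the conventional logBB cutoff of -1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ranger,
    e1071,
    nnet,
    caret,
    rpart,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
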