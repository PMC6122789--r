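Package: trajstate
Title: Temporal Classification of Model-Quality States in Protein
    Refinement Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies every snapshot of a molecular-dynamics refinement
    trajectory as an improved, no-change or decreased model-quality state
    relative to the starting model, using a stacked gated-recurrent-unit
    (GRU) network trained with a class-weighted cross-entropy loss under
    stateful truncated backpropagation through time. Includes per-target
    feature standardization, GDT_TS/RMSD/RMSF structure metrics from PDB
    coordinates, non-temporal baseline classifiers (random forest,
    k-nearest neighbours, logistic regression), class-balanced grouped
    cross-validation, Markov-chain and segment-length trajectory
    statistics, position/distance restraint and contact-map collective
    variable generation, and a synthetic trajectory generator with
    three-state Markov dynamics and autocorrelated feature emissions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    bio3d,
    ranger,
    glmnet,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
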