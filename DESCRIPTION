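Package: UmamiQSAR
Title: Umami Taste Classification from Molecular Structure by
    Evolutionary QSAR Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end QSAR pipeline for classifying molecules
    (peptides in particular) as umami or non-umami from their 2D
    structure. Parses SMILES, InChI and peptide FASTA inputs,
    standardizes structures, computes a 2D molecular-descriptor
    matrix including a native fragment-complexity descriptor,
    reduces dimensionality with a moderated t-test (empirical-Bayes
    variance shrinkage) and Benjamini-Hochberg FDR control, searches
    feature subsets, classifier family (SVM or random forest) and
    hyperparameters with a weighted multi-objective Pareto
    evolutionary algorithm under stratified 10-fold cross-validation
    with per-fold minority oversampling, averages pairs of models
    into ensembles, gates predictions with a Morgan-fingerprint
    Tanimoto applicability domain, and attributes predictions to
    individual descriptors with sampling-based Shapley values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
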