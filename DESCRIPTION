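Package: DrugBayes
Title: Bayesian Likelihood-Ratio Integration for Drug Target Identification
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates heterogeneous drug-drug similarity channels (growth
    inhibition profiles, post-treatment expression signatures, bioassay
    outcomes, side-effect terms and atom-pair structural fingerprints) into
    per-channel likelihood ratios and a total likelihood ratio (TLR) for
    shared-binding-target predictions under a naive Bayes evidence model.
    On top of the TLR it provides a weighted voting algorithm for specific
    protein-target prediction of orphan small molecules, a high-confidence
    prediction filter, cross-validated evaluation machinery (AUROC,
    Kolmogorov-Smirnov separation, true/false-positive ratio curves,
    leave-one-out voting accuracy), 1/TLR mechanism-of-action clustering,
    shared-target network construction, and a fully specified synthetic-data
    generator with planted drug-target ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    ape,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'data_io.R'
    'similarity.R'
    'bayes.R'
    'voting.R'
    'evaluation.R'
    'moa.R'
    'synthetic.R'
    'orchestration.R'
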