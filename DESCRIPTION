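Package: toxhybrid
Title: Prior-Knowledge Hybrid k-Nearest-Neighbour Models for Acute Aquatic Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening-level prediction of acute aquatic toxicity (LC50/EC50 in
    mg/L) for saturated aliphatic C/H/O/N compounds.  Implements standard
    k-nearest-neighbour predictors (Tanimoto similarity on circular
    fingerprints, Manhattan distance on molecular descriptors), a configurable
    prior-knowledge model composing a group-contribution fish model with a
    linear interspecies map, four hybridization schemes (molecular-weight
    outlier removal, knowledge-driven descriptor selection, logP-routed model
    switching, prior-knowledge-guided neighbour selection), and a rule-based
    post-assessment that audits models against literature toxicity trends via
    Spearman compliance matrices and a min-max rule-affinity score.  Also
    provides the literature sentence-mining step used to collect those trends
    and a synthetic-molecule generator for end-to-end benchmarking without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    readxl
Config/testthat/edition: 3
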