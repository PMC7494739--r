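Package: screenml
Title: Machine-Learning Rescoring for Structure-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating classifier-assisted
    structure-based virtual screening pipelines. Assembles per-compound
    feature tables from docking scores, pharmacophore fit values and
    molecular descriptors; reduces them with a four-step elimination
    cascade (near-constant counting filter, pairwise-correlation filter,
    two-sample t-test screen, principal-component reduction); trains
    support-vector or gradient-boosted-tree classifiers of actives versus
    decoys with stratified cross-validation; and simulates the downstream
    screening funnel (rule-of-five filter, pharmacophore prescreen, ranked
    docking cuts, fingerprint leader clustering, classifier rescoring)
    together with the enrichment metrics (ROC/AUC, accuracy, hit and
    exclusion rates, score-separation tests, redocking RMSD). A synthetic
    campaign generator with planted feature structure makes the whole
    pipeline testable without licensed docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
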