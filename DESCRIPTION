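Package: ddicl
Type: Package
Title: In-Context Learning and Judge-Weighted Ensembles for Drug-Drug
    Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting drug-drug interactions (DDIs) with large
    language models steered by in-context learning. Implements fingerprint,
    graph-kernel and embedding based drug similarity (Tanimoto, cosine, Dice,
    Weisfeiler-Lehman, embedding cosine), similarity-driven selection of
    positive and hard-negative prompt exemplars, structured zero-shot,
    few-shot and judge prompt construction, a pluggable prediction-backend
    contract with deterministic offline mock backends, judge-score weighted
    ensemble fusion, and cross-validated AUC/AUPR evaluation. A synthetic
    interaction-world generator with a planted structure-interaction coupling
    makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
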