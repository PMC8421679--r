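Package: thncdf
Title: Drug-Target Interaction Prediction with Similarity Fusion and a
    Cascade Deep Forest
Version: 0.1.0
Authors@R:
    person("THNCDF", "Maintainers", email = "maintainers@thncdf.dev",
           role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTI) from a tripartite
    drug-target-disease network. Chemical-structure similarity (Tanimoto
    coefficient over 166-bit structural-key fingerprints) is fused with
    Gaussian interaction-profile (GIP) kernels computed from drug-target
    and target-disease adjacency profiles, and drug-target pairs encoded
    by their fused similarity rows are classified with a cascade deep
    forest: stacked levels of completely-random, gradient-boosted and
    extremely-randomized tree ensembles whose out-of-fold class vectors
    augment the next level's input, with depth chosen automatically by
    validation gain. Includes readers for the Yamanishi-benchmark file
    dialect, a seeded block-model generator of synthetic tripartite
    networks, ranking metrics (AUC, AUPR) and a cross-validation driver,
    plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
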