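Package: l1mda
Title: Semi-Supervised miRNA-Disease Association Prediction via an L1-Norm Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations by semi-supervised
    label propagation on an L1-norm graph. Disease semantic similarity is
    computed from ontology (MeSH-style) directed acyclic graphs, miRNA
    functional similarity from association profiles (MISIM), and association
    scores are obtained by iteratively re-weighted Laplacian solves in both
    the miRNA and the disease space, then fused. Includes global and local
    leave-one-out cross-validation with ranking-based AUC, case-study style
    candidate ranking, seeded synthetic fixture generators, and TSV readers
    and writers for all interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
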