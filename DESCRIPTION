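Package: lipidmoe
Title: Mixture-of-Experts Discovery and Validation of Lipid Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discovering class structure in plasma lipidomics
    profiles and distilling sparse, validated lipid-marker panels. Implements
    computed ABC (cABC) analysis with nested re-application, emergent
    self-organizing maps (ESOM) with U-matrix clustering on a toroidal grid,
    a mixture-of-experts consensus feature-selection engine run inside
    repeated subject-grouped stratified cross-validation, holdout and
    permutation-controlled classifier validation with balanced accuracy and
    ROC-AUC percentile intervals, and the classical statistics used alongside
    (Kruskal-Wallis tests with multiplicity correction, Fisher's exact tests,
    lipid-class enrichment). Includes a synthetic lipidomics generator with
    known ground truth for end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
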