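Package: crosstalkDR
Title: Network-Guided Drug Repurposing for the Diabetes-Alzheimer Cross-Talk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested implementation of a drug-repurposing workflow that
    starts from layered RNA interaction networks (mRNA-miRNA, miRNA-lncRNA,
    drug-lncRNA), extracts high-degree hub miRNAs and lncRNAs by whole-tier
    accumulation, labels drugs as therapeutic or exacerbating from their
    directional effects on disease-shared lncRNAs, reduces PaDEL-style
    molecular descriptor matrices with a four-stage filter cascade (constant,
    correlation, entropy, t-test), trains a random forest classifier with
    out-of-bag tree-count selection and stratified cross-validation, and
    screens an external drug library through an applicability-domain filter
    (atom-count rule, leverage against the warning leverage 3p/n, one-class
    SVM) to rank repurposing candidates and adverse-drug warnings by class
    probability. Includes a synthetic-data generator with planted ground
    truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr,
    jsonlite
Config/testthat/edition: 3
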