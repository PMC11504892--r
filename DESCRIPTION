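Package: mirdiag
Title: miRNA Descriptor Generation and Bayesian Classification for
    Disease-Association Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sequence-, target-gene-, and pathway-based descriptors for
    mature microRNAs, ranks them by information gain with supervised MDL
    discretization, and trains discrete Bayesian-network and comparison
    classifiers to separate disease-associated miRNAs from background miRNAs
    under stratified cross-validation. Includes readers and writers for
    miRBase-dialect FASTA, miRDB-style target tables, pathway gene sets
    (TSV/GMT), and WEKA ARFF feature tables, plus a seeded synthetic-data
    generator with controllable class signal so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    foreign,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
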