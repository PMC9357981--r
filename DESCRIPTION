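Package: micomatch
Title: Iterative Matched Case-Control Consensus Analysis of Microbiome Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects gut-microbiome prevalence and abundance signatures of a
    rare future outcome (such as future celiac disease) in large,
    heavily imbalanced general-population infant cohorts. Implements an
    iterative matched case-control consensus procedure: confounders of
    beta diversity are screened by PERMANOVA on binomial-deviance
    distances, many seeded confounder-matched control subsets are drawn
    for the cases, and two statistical branches - a prevalence-interval
    core-microbiome filter ranked by random-forest out-of-bag
    permutation importance, and a negative-binomial Wald differential
    abundance test with zero-tolerant size factors - are run on every
    subset. Taxa significant in at least half of the iterations form
    the consensus signature. A synthetic-cohort generator with planted
    prevalence and fold-change effects makes the whole pipeline
    testable without access to cohort sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    vegan,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse,
    withr,
    knitr
biocViews: Microbiome, Metagenomics, DifferentialAbundance, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
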