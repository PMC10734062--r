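Package: cernet
Title: Competing Endogenous RNA Network Inference from Multi-Class
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers lncRNA/circRNA-miRNA-mRNA competing endogenous RNA
    (ceRNA) regulatory circuits from mRNA, lncRNA and circRNA expression
    matrices. Provides quantile normalization and sample-level quality
    control, fold-change plus t-test differential expression with a
    seven-region Venn partition across contrasts, a documented
    seed-match miRNA target predictor with import of external target
    tables, Pearson co-expression networks between differentially
    expressed sponge RNAs and mRNAs, circuit assembly by shared-miRNA
    evidence with optional hypergeometric stringency, filtering on
    X-chromosome-inactivation escape status of sponge host genes and on
    user-supplied gene sets, over-representation analysis, qPCR
    relative-quantification helpers, and a synthetic-data generator that
    plants known circuits with a truth manifest so every stage of the
    pipeline can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
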