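Package: geromir
Title: GeromiR Expression Analysis in the Liver Tumor Microenvironment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential miRNA analysis for two-condition microarray studies
    of the liver tumor microenvironment, centred on aging-associated miRNAs
    (geromiRs). Provides quantile normalization and matrix ingestion (including
    GEO series-matrix files), fold-change/significance differential-expression
    calling, a literature-curated geromiR catalog with aging-hallmark
    annotations and miRNA-name harmonization, hypergeometric over-representation
    statistics with a permutation oracle, a bipartite miRNA-target network
    screen for targets with reversed expression, a synthetic-data generator
    with planted ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
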