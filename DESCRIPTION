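Package: enrichkit
Title: Gene Set Enrichment Analysis with Permutation Nulls, ssGSEA and
    Offline Over-Representation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the weighted Kolmogorov-Smirnov running-sum
    enrichment statistic with gene-set and phenotype permutation null
    distributions, normalized enrichment scores, empirical p-values and
    GSEA-style FDR q-values; pre-ranked GSEA; single-sample GSEA (ssGSEA)
    scoring with cross-sample normalization; and offline over-representation
    analysis (Fisher exact test, Benjamini-Hochberg adjustment, odds ratio
    and Enrichr-style combined score). Reads and writes the community GMT,
    RNK, CLS and GCT formats, ships seeded synthetic-data generators with
    planted enriched gene sets so every statistic is testable without
    downloads, and provides a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
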