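Package: sigPCA
Title: Functionally Labeled Expression Signatures from Principal Components
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Unsupervised discovery of small, correlation-coherent expression
    signatures from a genes-by-samples expression matrix. Principal component
    analysis identifies the major axes of variation; for each component, genes
    ranked by loading are tested for gene-set enrichment with the exact
    nonparametric XL-mHG (minimum hypergeometric) test; enriched, filtered gene
    sets seed signatures whose per-sample expression is the unweighted mean of
    standardized member-gene expression. Includes OBO/GAF ingestion with
    annotation propagation, a permutation test for the number of components to
    test, local and cross-component redundancy filters, bootstrap robustness
    assessment, a synthetic-data generator with planted annotated modules, and
    plain-text readers and writers for all inputs and results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, pheatmap, grDevices
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
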