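Package: fhlcforest
Title: Forests of Hierarchical Latent Class Models for Linkage Disequilibrium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns forests of hierarchical latent class models (FHLCMs) from
    SNP genotype or haplotype matrices to model linkage disequilibrium and
    reduce data dimensionality. Variables are clustered layer by layer with a
    CAST clique-partitioning heuristic over binarized mutual-information
    matrices; each cluster is subsumed by a discrete latent variable fitted by
    EM, validated by an information-decay criterion, and imputed per
    individual. Includes evaluation metrics (dimension reduction rate, entropy
    compression rate, MRCA-level matrices, haplotype diversity), a
    block-structured LD simulator, exact sampling from a known model, forest
    serialization (GraphML/JSON/DOT), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    mclust,
    withr,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
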