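Package: xqtl
Title: X-Chromosome Heritability Partitioning and QTL Mapping from Allele Dosages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for studying the contribution of the X
    chromosome to complex traits in all-female cohorts, as practiced in dairy
    cattle genetics. Builds VanRaden-style genomic relationship matrices from
    allele dosages, partitions heritability into autosomal and X-linked
    components by two-variance-component average-information REML, runs
    mixed-linear-model association scans on imputed dosages with an
    eigendecomposition-based (EMMAX-style) approximation, combines scans
    across populations by fixed-effects inverse-variance meta-analysis, and
    delineates QTL regions with an iterative linkage-disequilibrium peeling
    procedure based on a conditional Wald statistic. A seedable
    founder-mosaic population simulator with distinct X-chromosome
    transmission (no male recombination) makes every stage testable without
    access to proprietary cattle data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
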