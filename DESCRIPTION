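Package: rohpan
Title: Phasing Diagnostics, Runs of Homozygosity and Pangenome
    Structural-Variant Analytics for Bovine Genomes
Version: 0.1.0
Authors@R:
    person("rohpan", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diploid genome diagnostics built around trio-binned
    assemblies and super-pangenomes of the Bovinae subfamily. Implements
    per-window trio-binning phase diagnostics (binnability and parental
    read bias), small-variant post-filtering with depth-based genotype
    masking, coverage-corrected windowed heterozygosity, run-of-homozygosity
    (ROH) calling with a relaxed-peak merge rule and the genomic inbreeding
    coefficient F_ROH, structural-variant presence/absence analytics from
    deconstructed pangenome VCFs (UpSet-style intersections, private-SV
    hotspot scans, pairwise-overlap distances and UPGMA trees), and
    normalized read-depth genotyping of candidate deletions. A seeded
    synthetic-data generator emulates the statistical structure of every
    input so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    data.table,
    GenomeInfoDb,
    graphics,
    jsonlite,
    stats,
    SummarizedExperiment,
    utils,
    VariantAnnotation,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
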