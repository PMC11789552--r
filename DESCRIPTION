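Package: hostshift
Title: Constitutive and Plastic Gene Expression Divergence Between Host Races
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dissecting constitutive
    versus plastic gene expression divergence between two host-specialised
    ecotypes under a cross-fostering design. Provides a seeded synthetic-data
    generator (negative-binomial read counts with planted effect classes and
    coexpression modules, gene models with a genomic inversion, and
    Balding-Nichols allele frequencies), count preprocessing, per-gene
    negative-binomial differential expression with empirical-Bayes fold-change
    shrinkage and s-value (false sign rate) inference, signed weighted
    coexpression networks (biweight midcorrelation, topological overlap,
    module eigengenes), eigengene-design scenario classification, windowed
    population-genomic scans (Bhatia F_ST, d_XY, nucleotide diversity,
    Tajima's D, composite outlier calls), and interval/gene-set enrichment
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    DESeq2
Config/testthat/edition: 3
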