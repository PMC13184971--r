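Package: magtraits
Title: Functional Traits, Prevalence Partitioning and Microdiversity of Genome-Resolved Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for genome-resolved (MAG-based) microbiome studies
    structured as two environments with replicated streams. Distills per-genome
    functional-identifier sets into genome-inferred functional traits (GIFTs,
    pathway-completeness scores in [0,1]) and community-weighted trait profiles;
    computes Hill-number alpha diversity (orders 0 and 1, neutral and
    phylogenetic), Jaccard-type turnover beta diversity, PCoA, PERMANOVA with
    permutation or exhaustive-enumeration p-values, multivariate dispersion
    tests and the domain-adjusted mapping rate; partitions genomes into core,
    endemic and marginal fractions from detection prevalence and runs
    fraction-wise functional comparisons; derives strain-level microdiversity
    (1 - population ANI) from consensus-allele tables. A synthetic-data
    generator with ground-truth annotation emulates the statistical structure
    of such studies so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
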