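Package: wgspop
Title: Population Genomics of Small Resequenced Cohorts: Diversity,
    Kinship, Selective Sweeps and Sex-Linked Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for conservation-genomic analysis of small whole-genome
    resequencing cohorts, with a synthetic-cohort generator carrying planted
    truth for validation. Implements GATK-style hard filtering and call-set
    intersection of biallelic SNVs, windowed nucleotide diversity and
    Tajima's D, runs of homozygosity and F_ROH, linkage-disequilibrium decay,
    method-of-moments inbreeding coefficients, identity-by-state and
    identity-by-descent kinship (DST, PI_HAT) with related-sample pruning and
    neighbour-joining trees, the ABBA-BABA D statistic with block jackknife,
    a dual-statistic selective-sweep scan (pooled heterozygosity zHp and
    Weir-Cockerham F_ST with top-quantile overlap), read-depth-based Z/W
    scaffold classification and sample sexing for female-heterogametic birds,
    short-tandem-repeat marker selection (polymorphism information content,
    kinship and sex panels), deleterious-load proportions, and
    divergence-based mutation-rate estimation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    vcfR,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
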