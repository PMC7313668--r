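Package: hybridscan
Title: Ploidy, Heterozygosity and Copy-Number Analysis for Hybrid Yeast
    Population Genomics
Version: 0.1.0
Authors@R:
    person("Avery", "Delmas", email = "avery.delmas@example.org",
           role = c("aut", "cre"))
Description: Population-genomic analysis of diploid and allotriploid yeast
    isolates from variant calls and read-depth tracks: ploidy inference from
    the allele-balance distribution at heterozygous sites, detection of
    loss-of-heterozygosity regions by sliding-window scan, windowed nucleotide
    diversity statistics (pi, Watterson's theta, Tajima's D) on
    IUPAC-encoded alignments, BioNJ phylogeny with heterozygosity-aware
    average-state distances, read-depth copy-number segmentation with
    gene-level copy numbers and triploid subgenome attribution, and
    core/accessory pangenome classification. Includes a synthetic-population
    generator that emulates the variant-call-level structure of hybrid yeast
    cohorts so every stage can be exercised and validated against ground
    truth without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    ape,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
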