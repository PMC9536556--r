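Package: famshare
Title: Family-Based Variant Prioritization and Identity-by-Descent Sharing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for family-based whole-genome variant prioritization and
    shared-segment analysis. Implements a multi-predictor "casting vote"
    deleteriousness consensus with rarity, consequence and affected-carrier
    filters, per-family candidate-gene reports and their cross-family
    intersection; filtering and gene annotation of pairwise
    identity-by-descent (IBD) segments with within- and cross-family sharing
    tables and a simple genotype-based segment detector; cross-population
    per-gene pathogenic-burden and minor-allele-frequency spectrum
    statistics; and a pedigree gene-drop simulator (recombination,
    monozygotic twins, planted pathogenic variants, multi-population
    frequency panels, predictor status matrices) so every stage can be
    exercised end to end on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
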