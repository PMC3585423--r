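Package: mirsat
Title: Simulation and Depth-Aware Analysis of Small RNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how sequencing depth, library composition and
    analysis choices shape mature miRNA quantification in small RNA-seq.
    Provides a seeded synthetic-library generator with a per-read ground-truth
    ledger (mixed mature-miRNA / structured-ncRNA / repeat / unclassified /
    adapter-dimer composition, long-tailed abundance, 3' isomiR variation,
    single-substitution sequencing errors and adapter read-through); 3' adapter
    clipping, length filtering and read collapsing; a single-SNV-tolerant
    quantifier with an isomiR "others" ledger, EM redistribution of
    multi-mapping reads and RPM normalization; detection-saturation and
    Spearman correlation-adequacy curves under nested subsampling; and
    count-based two-group differential expression (TMM and median-of-ratios
    normalization, common-dispersion negative-binomial exact test,
    Benjamini-Hochberg FDR control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
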