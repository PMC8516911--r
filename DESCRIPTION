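Package: quadmine
Title: Mining DNA G-Quadruplexes from Sequencing Quality Drops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects DNA G-quadruplex-forming loci genome-wide from ordinary
    whole-genome resequencing data. Unstably folded quadruplexes perturb
    sequencing chemistry and leave a localized drop in per-locus median base
    quality on the quadruplex strand. quadmine builds strand-specific median
    quality tracks from aligned reads, scans them with a two-threshold
    low-quality-region rule, calibrates the scan thresholds against predicted
    canonical quadruplex motifs under a false-positive-rate constraint, and
    classifies the mined regions into structural families (canonical, long
    loops, bulges, two tracts, others). It also quantifies the effect of
    single-nucleotide variants on quadruplex formation, both by re-predicting
    motifs on an edited genome and by allele-split calling at heterozygous
    sites, and ships a read simulator with a per-read quality-drop model so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    data.table,
    jsonlite,
    methods,
    yaml,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
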