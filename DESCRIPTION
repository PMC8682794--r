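Package: g4cnv
Title: Read-Depth CNV Detection, G-Quadruplex Association and Fluctuation
    Analysis for Yeast Genome-Instability Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for studying copy-number instability
    at G-quadruplex (G4) loci in budding yeast. Implements GC-normalized
    read-depth copy-number-variant (CNV) detection on overlapping sliding
    windows (robust-regression GC correction, per-window chi-squared tests
    against a control strain, Benjamini-Hochberg FDR, interval merging with
    size and support filters, whole-chromosome duplication flags, and
    mitochondrial copy number from RPKM ratios); G4 motif scanning and
    interval-overlap enrichment with exact tests and a matched resampling
    null for distances to G4 elements; Luria-Delbruck fluctuation analysis
    by Ma-Sandri-Sarkar maximum likelihood with profile-likelihood
    confidence intervals and rate fold-enrichment; Pfaffl efficiency-
    corrected qPCR enrichment; thermal difference spectrum computation and
    G4-signature classification; and Langmuir binding-kinetics fitting for
    label-free biosensor curves. A seeded synthetic-data module generates
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    limma,
    Rsamtools,
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
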