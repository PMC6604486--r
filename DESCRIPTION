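Package: mipsurvey
Title: Genome-Wide Survey of Plant Aquaporin (MIP) Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide surveys of the plant
    aquaporin (major intrinsic protein, MIP) gene family. Screens candidate
    proteins against a curated reference set by pairwise global-alignment
    identity and coverage, assigns subfamilies (PIP, TIP, NIP, SIP, XIP) and
    standardized paralog nomenclature, profiles structural hallmarks
    (transmembrane helices, NPA boxes, the ar/R selectivity filter and
    Froger's positions), summarizes exon/intron architecture, detects tandem
    gene duplications under a window rule, estimates Ka/Ks by the
    Nei-Gojobori (1986) codon-counting method, builds neighbor-joining trees
    with bootstrap supports, classifies tissue and salt-stress expression
    patterns from FPKM matrices, and quantifies qPCR results by the
    2^-ddCt method. Ships a synthetic-data generator that plants ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
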