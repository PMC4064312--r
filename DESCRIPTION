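Package: panelseq
Title: Somatic Alteration Calling and Cohort Statistics for Targeted Tumor Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for hybrid-capture targeted tumor sequencing:
    Bayesian base-substitution calling from allele pileup counts with
    hotspot-aware site priors, insertion/deletion detection by de Bruijn
    local assembly of exon reads, purity- and ploidy-aware copy-number
    calling from exon log-ratio profiles and heterozygous-SNP allele
    fractions, viral read-count classification of HPV status, and
    cohort-level alteration-enrichment and clustering statistics. Includes a
    fully ground-truthed synthetic cohort simulator for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    generics
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
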