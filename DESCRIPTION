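Package: deuteromics
Title: Downstream Statistics for Metagenomic ORF Tables from Extreme Aquatic Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for the downstream analysis of per-ORF metagenome
    summary tables: TPM normalization and abundance-weighted gene-length
    statistics, species richness and Jaccard beta-diversity, annotation
    censuses (transposase prevalence, per-gene TPM matrices, orphan
    fraction), relative amino-acid composition with two-group enrichment
    tests, Nei-Gojobori (1986) ka/ks estimation with codon-pathway
    averaging and Jukes-Cantor correction, and a power-law
    abundance-richness model with delta deviation diagnostics. Includes
    seeded synthetic-data generators for every input so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
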