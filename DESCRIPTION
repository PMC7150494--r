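Package: aasig
Title: Aristolochic Acid Mutational Signature Screening for Urothelial Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen tumour and urinary cell-free DNA sequencing data for
    the aristolochic acid (AA) mutational process in upper tract urothelial
    carcinoma. Implements post-calling somatic SNV filtering (caller
    intersection, eight read-level artifact rules, allele-frequency window,
    population-frequency removal with pathogenicity rescue), construction of
    96-trinucleotide-context mutation catalogs, non-negative least squares
    refitting of catalogs onto reference mutational signatures with
    etiology-based merging, AA-subtype assignment by hierarchical clustering or
    proportion thresholds, binomial thinning to emulate low-coverage calling,
    clinical association tables, Kaplan-Meier and log-rank survival comparisons,
    and seed-deterministic synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
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
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    mclust,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
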