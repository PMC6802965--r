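Package: cregrammar
Title: Comparative Cis-Regulatory Grammar Analysis of Open Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the cis-regulatory grammars of related cell
    classes from open-chromatin (ATAC-seq/DNase-seq) peaks and matched
    transcriptomes. Implements IUPAC consensus motif scanning, motif
    enrichment, co-occurrence and spacing statistics, negative-binomial
    differential accessibility and expression testing with a rule-based
    photoreceptor-contamination filter, interval algebra (peak unions,
    promoter/enhancer classification, nearest-TSS assignment,
    tissue-specificity filtering), accessibility-expression quadrant
    integration, and pseudo-bulk aggregation of clustered single-cell
    counts. A synthetic-data module generates genomes, peak sets and count
    matrices with planted ground truth so every stage is testable end to
    end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
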