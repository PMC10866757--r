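Package: codonrca
Title: Codon Usage Analysis and Synonymous Transgene Design with the
    Relative Codon Adaptation Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds codon-usage reference tables from highly expressed
    coding sequences selected out of an RNA-seq count matrix
    (median-of-ratios normalization, TPM, time-point stability filtering,
    ranking), scores coding sequences with the reference-set-based
    relative codon adaptation (RCA) index and the codon adaptation index
    (CAI), and designs synonymous gene variants: fully codon-optimized,
    adaptation-minimized under an exact GC-content constraint (dynamic
    programming), AT-rich, and signal-peptide/ER-retention fusions.
    Includes a seeded synthetic-data generator with known ground truth so
    the whole pipeline can be exercised and validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
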