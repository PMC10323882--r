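Package: codonstate
Title: State-Adapted Codon Usage Analysis and Synonymous Recoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build codon-usage frequency tables for cell-state-specific gene
    sets, score a coding sequence's adaptation to each state as the squared
    Pearson correlation of per-codon frequencies, and design synonymously
    recoded sequences by cross-state frequency matching (each sense codon is
    replaced by the synonym whose target-state frequency best approximates the
    original codon's source-state frequency). Includes a seeded synthetic-data
    generator of state table pairs and codon-sampled coding sequences with
    known ground truth, a calibration routine for the maintenance tolerance,
    sequence diffing, plain-file (FASTA/TSV/JSON) interfaces and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
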