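Package: ivmseq
Title: Transcriptome and Outcome Comparison of In Vitro Versus In Vivo
    Matured Oocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for comparing transcript abundance between in
    vitro matured (IVM) and in vivo matured (IVV) oocytes from run-level
    RNA-seq count tables: library-size ratio normalization with technical-run
    summing, a pooled-variance confidence-interval detection threshold,
    three-filter differential calling (detection threshold, Student's t-test,
    fold change), a marker-based contamination check, hypergeometric gene-set
    over-representation, comparative-CT (2^-ddCt) qPCR quantification with
    primer-efficiency curves, and maturation/cleavage/blastocyst outcome
    statistics. Includes seeded synthetic-data generators that reproduce the
    replicate structure of the experimental design for validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
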