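Package: anatlas
Title: Tissue- and Sex-Resolved Expression Atlas Analysis for Anopheles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical pipeline for a tissue- and sex-resolved gene
    expression atlas of the malaria mosquito Anopheles gambiae: probe-level
    present/absent detection calls from perfect-match/mismatch signals,
    moderated linear-model tests of sexually dimorphic expression and gonad
    enrichment, tissue-breadth scoring with the tau statistic, chromosome-arm
    distribution tests, SNP-based A/S (pN/pS) selection estimates with
    Nei-Gojobori site counting and gene bootstrap confidence intervals, and
    cross-species expression-conservation analysis (relative-abundance
    profiles, co-expression clusters, hypergeometric cluster overlap,
    bootstrap-supported tissue dendrograms, gene-family origin and copy-number
    classification). Ships synthetic-data generators with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    yaml
Config/testthat/edition: 3
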