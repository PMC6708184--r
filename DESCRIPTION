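Package: gridtill
Title: Screening-by-Sequencing for Two-Dimensionally Pooled EMS TILLING Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reverse-genetics screens of chemically mutagenised
    (EMS) plant populations by pooled amplicon sequencing. Simulates
    mutant populations with the G/C-to-A/T-biased EMS spectrum and the
    pooled read-count structure of equimolar two-dimensional
    (row-by-column) DNA pools; detects candidate mutations in pools with
    relaxed allele-fraction thresholds; deconvolutes pool-level hits to
    individual plants by the one-row-one-column intersection rule;
    infers zygosity from pooled allele fractions; annotates variant
    effects against gene models; and computes population
    characterisation statistics (mutation spectrum, mutation density,
    hard-filter cascades, capture-probe tiling arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
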