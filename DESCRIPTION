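Package: tcgi
Title: Dual-Guide tRNA-Spaced CRISPR Screens: Library Design, Simulation,
    Deconvolution and Genetic-Interaction Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anchored dual-guide CRISPR genetic-interaction screens in
    which two sgRNAs are expressed from one transcript separated by a tRNA
    spacer. Covers in-silico design of the Golden-Gate half-oligo library and
    its overlap assembly, simulation of pooled differential-growth screens with
    a known truth table, deconvolution of paired sequencing reads into
    construct-level count matrices, background correction and TMM-normalized
    negative-binomial differential abundance, single-effect-adjusted
    ratio scoring of genes synergistic with an anchor gene, amplicon indel
    quantification, and Bliss-independence drug-synergy statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    edgeR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
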