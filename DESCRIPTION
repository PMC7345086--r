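Package: codonchron
Title: Chronological Analysis of the Universal Genetic Code by Codon GC-Richness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Orders the 64 codons of the universal genetic code and their
    cognate amino acids from GC-rich (inferred early) to AU-rich (inferred
    late), partitions them into three chronological groups, overlays
    aminoacyl-tRNA synthetase (aaRS) class I/II assignments to detect zonal
    structure with a permutation clustering statistic, compares the
    GC-derived chronology to published amino-acid chronologies using
    tie-aware rank correlation, and provides a stochastic simulator of
    bridge-peptide mediated aminoacylation in a GC-biased RNA-peptide world.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
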