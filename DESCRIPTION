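Package: phascreen
Title: Degenerate Primer Design and In Silico PCR Screening for PHA
    Synthase (phaC) Gene Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular screening of the four classes of
    polyhydroxyalkanoate (PHA) synthase (phaC) genes with degenerate
    primers. Implements the algebra of IUPAC ambiguity codes (degeneracy,
    expansion, reverse complement), mismatch-tolerant primer-template
    matching with an end-partitioned mismatch budget, library coverage
    statistics, a greedy expansion/contraction heuristic for designing
    degenerate primers under a degeneracy cap, thermodynamic primer QC
    (GC content, Wallace and nearest-neighbor melting temperatures,
    self- and 3'-annealing scores), in silico PCR with product-size
    filtering and non-specific product flagging, panel-based class
    assignment producing screening matrices, and a synthetic sequence
    generator with planted primer-binding sites and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
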