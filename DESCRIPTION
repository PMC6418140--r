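Package: mircurate
Title: Rule-Based Curation, isomiR Typing and Expression Analysis of Plant miRNA Candidates
Version: 0.1.0
Authors@R: person("mircurate", "developers", role = c("aut", "cre"),
    email = "mircurate@example.org")
Description: Curates candidate plant miRNA hairpins from small-RNA read stacks.
    Parses dot-bracket secondary structures, infers star strands from Dicer duplex
    geometry, scores duplex mismatches, asymmetric bulges and 3' overhangs, and
    applies a seven-rule confidence scheme (with a precise-excision rescue clause)
    to call high-confidence and very-high-confidence miRNAs. Also assigns
    conserved/novel status against a known mature set, detects and types isomiRs
    (5'/3' shifts, templated and nontemplated 3' modifications, internal
    polymorphisms), quantifies expression with windowed read counting, normalizes
    to TPM, flags differential expression with a simplified negative-binomial Wald
    test and Benjamini-Hochberg correction, and ships a synthetic small-RNA-seq
    generator with planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
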