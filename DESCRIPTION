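Package: lcprofiler
Title: Consensus-Matrix Profiling of Antibody Light-Chain Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing monoclonal (AL amyloidosis, multiple myeloma)
    and polyclonal antibody light-chain variable-domain sequences on the fixed
    127-position IMGT scaffold. Builds per-germline-gene residue consensus
    matrices (including gaps as a 21st symbol), classifies residues as common,
    uncommon or rare against a polyclonal reference, computes per-sequence
    frequency profiles, difference matrices, per-position Gini diversity,
    Euclidean distances with hierarchical clustering, and modified
    sequence-logo data. Provides per-position and per-pattern 2x2 enrichment
    statistics with an additive 0.1 count correction, Wald confidence
    intervals, Benjamini-Hochberg FDR control and a germline-only artifact
    filter, together with parsers and counters for published residue-change
    patterns (gain/loss/exact substitutions and the CDR3 proline insertion)
    and a seeded synthetic repertoire generator with planted enrichment
    effects for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
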