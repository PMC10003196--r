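Package: gatemap
Title: Interdomain Salt-Bridge, Coordination-Site and Inactivation-Kinetics
    Analysis for Calcium-Selective TRP Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for state-dependent conformational comparison of
    ion-channel structure ensembles and molecular-dynamics trajectory frames.
    Reads multi-model PDB coordinate files, measures salt-bridge proxy
    distances between terminal charged side-chain atoms of residue pairs,
    aggregates them into state-comparison tables, detects putative calcium
    coordination sites by an oxygen-count geometry rule, computes Kabsch
    superposition RMSD series with stability-onset detection, scores
    per-column clade-group conservation of protein alignments with
    fingerprint-position detection, and fits single-exponential inactivation
    kinetics (residual current and time constant) to whole-cell current
    traces. A seeded synthetic-data module generates every input class with
    known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
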