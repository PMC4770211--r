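Package: medidr
Title: Intrinsic Disorder Evolution Analysis of the Mediator Complex
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of intrinsic disorder across the subunits of the
    eukaryotic Mediator complex: parsing per-residue disorder score tables
    (IUPred-style), calling intrinsically disordered regions (IDRs) with a
    gap-tolerant run rule, assigning IDRs to N-terminal/middle/C-terminal
    thirds and classifying their per-kingdom conservation, neighbor-joining
    clustering of organisms from subunit-average disorder, Mann-Whitney
    comparisons of disorder between kingdoms with Table-style rank-order
    summaries, post-translational-modification enrichment in IDRs and
    sliding-window PTM hotspot detection, MoRF segment calling with
    alignment-based conservation and junction-MoRF flagging, interaction-hub
    classification from edge lists, and a fully seeded synthetic-data
    generator emulating the multi-kingdom study design so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
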