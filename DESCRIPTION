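Package: mirtracker
Title: Track microRNA Annotation Changes Across miRBase Releases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests a series of miRBase annotation releases (miRNA.dat EMBL
    flat files, mature.fa FASTA files and miRNA.dead removal records), detects
    and classifies every per-record annotation change (additions, renames,
    sequence revisions, relationship changes, deletions, merges and
    resurrections), persists the changes in a replayable two-table event store,
    and answers history, update/reannotation and release-comparison queries.
    Includes a retro-accession reconciler for early releases in which mature
    miRNAs carried no accession numbers, a synthetic release-series simulator
    with a machine-readable ground-truth change log for fully offline testing,
    and a canonical seed-match target predictor used to quantify how sequence
    annotation changes turn over a miRNA's predicted targetome via a
    prediction-overlap ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
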