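Package: proTRN
Title: Condition-Specific Transcriptional Regulatory Networks from
    Co-Expressed Protein Profiles and Promoter Motif Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers condition-specific transcriptional regulatory networks
    for bacteria from co-expressed protein profiles and per-gene promoter
    motif count matrices. Provides an exact dynamic-programming p-value
    engine for position-specific scoring matrices, promoter scanning with
    stringency tiers and automatic most-stringent site selection, motif
    matrix clustering with a clustered-TF filter, a three-step network
    construction, normalized structural network properties compared against
    Erdos-Renyi null ensembles, regulatory hierarchy decomposition by
    out-connectivity, and detection of condition-specific isoenzyme
    multiplicity from KEGG Orthology mappings. A synthetic-data generator
    with planted regulons, motif sites and KO groups makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
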