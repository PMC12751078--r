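Package: ppiconserve
Title: Cross-Database Consolidation and Evolutionary Conservation Analysis of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to harmonize protein-protein interaction (PPI) database
    snapshots (PSI-MITAB and edge-list input), quantify cross-database
    concordance (exclusive UpSet-style intersections, Szymkiewicz-Simpson
    overlap coefficients), test robustness of database disagreement under
    greedy sequence-identity clustering, map interactions onto ortholog-group
    pairs to measure cross-species conservation spans, quantify PDB
    structure-coverage enrichment as odds ratios against a non-conserved
    baseline, extract conserved interaction networks, and analyse structural
    ensembles of complexes (Kabsch superposition, per-residue RMSF,
    inter-chain contact frequency, TM-score). Includes a synthetic-data
    generator that emits every input format the pipeline reads, with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
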