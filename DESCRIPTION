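Package: gagmap
Title: Site-Mapping and Ensemble Analysis of Protein-Glycosaminoglycan Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how proteins recognise glycosaminoglycans
    (GAGs) from structural ensembles and docking pose sets. Reads multi-model
    PDB ensembles of protein-glycan complexes, detects hydrogen bonds with
    geometric distance/angle criteria and aggregates them into per-frame
    occupancy fractions, ingests per-residue pairwise energy-decomposition
    tables (AMBER MMPBSA-style CSV or a canonical TSV) and assembles
    three-channel (H-bond / electrostatic / van der Waals) site-maps over
    protein residues and sugar rings, with normalisation, comparison and
    correlation utilities. Also provides pose geometry metrics (RMSD,
    atom-type-matched RMSD, orientation classes), bound-pose filtering,
    DBSCAN clustering with medoid representatives, and ranking of ligands
    from ensembles of binding free-energy values including rank-occurrence
    tables and pairwise Welch tests. A synthetic-data generator produces
    toy complexes, pose sets and energy tables with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
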