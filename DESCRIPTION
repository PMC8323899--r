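Package: prnkit
Title: Protein Residue Network Construction and Interface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds protein residue networks (PRNs) from PDB structures
    (distance-based networks) or from residue/fragment pair interaction
    energies (Gamess FMO output with optional PIEDA components, or
    force-field energies evaluated from an Amber topology), and analyses
    them: node and edge centralities including a total-energy centrality,
    weighted global/local efficiency and efficiency centrality, residue
    folding degree, shortest paths, Louvain and spectral partitions.
    Supramolecular complexes are split into monomer and bipartite
    interface subgraphs for network differential analysis (NDA),
    singular-value-decomposition interface motifs, scattered pair
    interaction energy (SPIE) tables and per-fragment binding energies.
    Graphs export to GEXF and GraphML; synthetic toy complexes and
    pseudo-FMO files make every analysis testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    bio3d,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
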