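Package: pocketome
Title: Grid-Based Pocket Detection and Ligandability Mapping for Protein-Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ligandable binding pockets on two-chain protein-protein
    complexes with a voxel-grid method combining burial (ray-casting) and
    hydrophobic molecular-interaction-field energies, smooths candidate
    regions by morphological opening, and classifies pockets as interface,
    allosteric-like or equilibrium according to their relation to the
    interaction partner. Maps crystallographic-ligand occupancy across
    superposed homologous structures, computes geometric and energetic
    pocket descriptors (globularity, rugosity, hydrophobic and hydrophilic
    volume, buried volume, solvent exposure), validates predicted pocket
    residues against known binding residues with the Matthews correlation
    coefficient, and assembles per-cancer interaction networks with hub
    identification. Includes a synthetic-structure generator with
    analytically known cavities for offline testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    igraph,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
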