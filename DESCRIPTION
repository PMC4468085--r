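Package: kinnet
Title: Residue Interaction Networks, Coevolution and Binding Energetics
    for Protein Kinase Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links inhibitor binding to the residue interaction network of a
    protein kinase.  Provides ensemble dynamics statistics (superposition,
    B-factors, principal component analysis, cross-correlations, anisotropic
    network model modes), side-chain contact counting and Shrake-Rupley
    solvent accessibility, interaction-strength network construction with
    correlation-weighted betweenness centrality, MM-GBSA binding free energy
    decomposition with computational alanine scanning on a minimal
    molecular-mechanics backend, and mutual-information coevolution scoring
    (MI, KL conservation, cMI, pMI) from multiple sequence alignments.
    Seed-controlled generators of toy structures, correlated conformational
    ensembles, planted-coevolution alignments and ligand-bridged complexes
    exercise the full pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
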