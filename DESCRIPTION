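Package: ecrflip
Title: Energy Centrality Classification of Protein-Protein Interfaces
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distinguishes functionally linked protein-protein interfaces
    (FLIPs) from functionally uncorrelated contacts (FunCs) using the energy
    centrality relationship: per-residue computational alanine-scanning
    free-energy changes (ddG) are regressed against each residue's distance
    from the centre of the interface, yielding eight energetic and geometric
    features per interface that are classified by a two-round
    standardized-PCA plus k-means (k = 2) procedure.  Includes PDB interface
    detection built on 'bio3d', ddG table ingestion, projection of new
    interfaces through a trained model, confusion-matrix metrics (accuracy,
    Matthews correlation coefficient), random sub-sampling validation, and a
    synthetic interface generator for end-to-end testing without external
    structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
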