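Package: rinmap
Title: Residue Interaction Network Fingerprints and Autoencoder Maps for
    Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts each frame of a protein molecular dynamics trajectory
    into a residue interaction network (RIN) using a minimum inter-atomic
    distance criterion, extracts per-residue closeness centrality
    fingerprints, and embeds the fingerprint time series into a
    two-dimensional conformational map with an autoencoder trained on a
    combined reconstruction and sigmoid-transformed pairwise-distance cost.
    Includes collective-variable calculators (radius of gyration, RMSD after
    Kabsch superposition, helix RMSD, vertical shift, domain contact score,
    map density) for interpreting the maps, a synthetic two-state toy
    trajectory generator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ggplot2,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
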