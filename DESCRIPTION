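Package: enmodes
Title: Coarse-Grained Elastic Network Analysis of Protein Motion Modes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gaussian network model (GNM) and anisotropic network model (ANM)
    analysis of protein structures coarse-grained to C-alpha nodes. Builds
    Kirchhoff and Hessian matrices from a distance-cutoff contact network,
    eigendecomposes them, and derives per-residue mean-square fluctuations,
    slow-mode profiles with hinge detection, residue cross-correlation maps
    over a chosen mode range, and directional displacement fields for the
    slowest anisotropic modes. Includes a Kabsch superposition routine with
    per-residue deviations and helix bend-angle measurement for comparing
    conformations, a minimal PDB C-alpha reader/writer, an NMD exporter for
    normal-mode viewers, and a synthetic C-alpha structure generator (chains,
    rings, helices, bundles, two-domain dumbbells, gapped chains) so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    igraph,
    jsonlite,
    yaml,
    tools,
    utils,
    stats,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
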