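Package: cryoscore
Title: Goodness-of-Fit Assessment of Atomic Models in Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing rigid and flexible fits of atomic models in
    three-dimensional electron microscopy density maps. Reads and writes
    CCP4/MRC density maps and PDB atomic structures, simulates density maps
    from coordinates by Gaussian blurring, and scores model-to-map agreement
    with a family of global and segment-based goodness-of-fit measures:
    cross-correlation (CCC, SCCC, Laplacian-filtered), mutual information
    (MI, SMI), envelope overlap (ENV), surface normal-vector angle (NV and
    its Sobel-filtered variant NV-S) and Chamfer distance (CD). Supports
    generation of local rigid-body fit ensembles, hierarchical C-alpha RMSD
    clustering of fits, and Borda-count consensus re-ranking across scores,
    plus per-residue attribute files for molecular-graphics colouring.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
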