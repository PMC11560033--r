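Package: gpcrmech
Title: Quaternion-Based Analysis of GPCR Activation in Stressed Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for steered molecular-dynamics studies of
    G protein-coupled receptor (GPCR) mechanosensitivity, modelled on the
    angiotensin II type 1 receptor. Provides a quaternion description of
    transmembrane-helix reorientation, Ballesteros-Weinstein residue
    mapping over multi-model PDB trajectories, conformational-state
    classification from inter-helix distances, lateral pressure profile
    processing, membrane property measures (thickness, area per lipid,
    acyl-chain order parameters, surface tension), protein cross-section
    area profiles and the work integral against the lateral pressure
    profile, lipid-receptor hydrogen-bond and internalization detectors,
    a toy rigid-helix steering simulator, and synthetic-data generators
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
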