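Package: mwcolon
Title: Simulated Microwave Colonoscopy Imaging and Polyp Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: In-silico model of a microwave colonoscopy accessory: simulates
    the multistatic measurements of an 8+8 antenna ring at 7.5 GHz pulled
    through a synthetic colon with polyps, stool remnants and wall-contact
    events (Born-approximation forward scattering in a lossy homogeneous
    background), reconstructs per-frame dielectric-contrast images by
    adjoint backprojection, classifies frame validity from channel
    mismatch, detects polyps versus stool by thresholding and run-width
    classification on the concatenated contrast map, and scores alerts
    against ground-truth annotations at the segment level.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
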