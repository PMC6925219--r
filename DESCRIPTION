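Package: vesselquant
Title: Quantification of Blood-Brain-Barrier Leakage and Microglia-Vessel
    Interaction in Two-Photon Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for in vivo two-photon microscopy of the
    cerebral vasculature: translation registration of time-lapse frames,
    maximum-intensity projection and cortical depth-window selection, vessel
    delineation by maximum-entropy (Kapur) thresholding with particle-size
    filtering, blood-brain-barrier permeability indexing from extravascular
    dextran fluorescence, a dual-channel line-profile classifier for
    vessel-associated microglia, Pearson colocalization, skeleton-based
    microglial morphometry (process counts and lengths, soma area, puncta
    positivity, pericyte coverage) and process-tip motility in registered
    time-lapses. Includes a synthetic scene generator that renders vessels,
    ramified microglia, extravascular leak halos, puncta and realistic
    Poisson-Gaussian noise with full ground truth, so every stage is testable
    end to end without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
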