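Package: fociscope
Title: Detection and Characterization of False-Positive Nuclear RNA Foci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for nuclear RNA foci in fluorescence
    microscopy, built around signal-to-background-ratio (SBR) spot calling
    with an empirical-null threshold calibrated on mock (focus-free) control
    cells. Provides maximum-intensity projection and photobleaching
    correction, Laplacian-of-Gaussian candidate detection, per-cell foci
    counting, two-channel colocalization (pixel Pearson correlation and
    object-level spot matching with a physical distance criterion),
    condensate liquid-property readouts (circularity, fusion-event tracking
    with intensity conservation, condition comparisons with Welch/ANOVA and
    Dunnett's T3-style post hoc tests), and a synthetic-microscopy scene
    generator with known ground truth (anisotropic Gaussian PSF,
    Poisson-Gaussian noise) used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    jsonlite,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
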