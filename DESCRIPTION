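Package: smflim
Title: Wide-Field Single-Molecule Fluorescence-Lifetime Imaging with a
    Two-Gate Single-Photon Camera
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of wide-field single-molecule
    fluorescence-lifetime imaging (smFLIM) acquired with an alternating
    two-gate single-photon (SPAD) camera. Provides a photon-level simulator
    of q-bit gated frame stacks (binomial binary-frame counting, Gaussian
    point-spread functions, warm pixels, stochastic photobleaching and
    acceptor-bleach FRET steps), the two-gate rapid-lifetime-determination
    estimator with background subtraction and pile-up correction, the
    closed-form shot-noise F-value theory with optimal gate-delay design,
    and a full single-molecule trace pipeline: warm-pixel masking,
    Laplacian-of-Gaussian spot detection, box trace extraction,
    photobleaching step segmentation, trace classification, static and
    dynamic lifetime estimation, and lifetime- and intensity-based FRET
    efficiency readout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
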