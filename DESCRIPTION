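Package: gaitcode
Title: Decoding Locomotion from Granule-Cell Synaptic Input and Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking single cerebellar granule-cell synaptic
    input and spike output to locomotion: motion-energy video quantification,
    threshold-based synaptic event detection, decomposition of voltage-clamp
    traces into fast phasic EPSCs and a slow glutamate-spillover baseline
    (cubic-spline plus biexponential-train fit), step-cycle modulation and
    phase-tuning analysis, shuffle-bootstrap significance machinery, an
    unsupervised two-state hidden Markov model that reconstructs the
    swing/stance sequence from single-cell activity, and a conductance-based
    point-neuron granule-cell surrogate. Includes a seeded synthetic-recording
    generator with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    splines,
    stats,
    utils,
    graphics,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
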