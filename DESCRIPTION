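Package: spinalcode
Title: Quantification of Spinal Sensorimotor Circuit Function from Sensory Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for spinal sensorimotor circuit physiology:
    parametric muscle and skin stimuli with a viscoelastic muscle-force model,
    a battery of 31 spike-train encoding parameters per sensory neuron,
    ensemble population rate codes, a PCA latent encoding space with group
    ellipses and treatment-shift vectors, stagewise and compounded circuit
    representation accuracy (percent variance accounted for), conjugate
    Beta-binomial inference on detection proportions with highest-density
    intervals, and ladder-rung walking kinematics from pose-tracker exports.
    Includes a synthetic-data generator emulating control and chronic
    oxaliplatin-induced neurotoxicity (cOIN) phenotypes for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
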