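Package: gaitprofile
Title: Gait Profile Score Analysis with Direct and Multibody-Optimisation Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clinical gait analysis comparing two joint-kinematics
    engines: a conventional direct (Cardan) approach that builds segment frames
    straight from surface markers, and a global-optimisation inverse-kinematics
    approach that fits a constrained lower-limb skeletal chain to all markers
    simultaneously. Provides a parametric lower-limb model with anthropometric
    scaling and knee-axis adjustment, a synthetic gait-laboratory data
    generator with soft-tissue-artefact noise, Gait Variable Score / Gait
    Profile Score metrics, foot progression angle, symmetry index, and the
    outcome statistics used to compare engines and classify surgical
    responders against a minimal clinically important difference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
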