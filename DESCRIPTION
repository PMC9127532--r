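Package: qwpso
Title: Quantum and Wormhole-Behaved Particle Swarm Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Grayscale image segmentation by quantum-behaved particle swarm
    optimization (QPSO) and its wormhole-behaved extension (QWPSO), in which
    distant clusters of similar intensity are linked through a hyperbolic
    "wormhole" path measure. Includes the delta-potential-well sampling law,
    the hyperbolic disc embedding with angular-separation bound, an
    intensity/distance seeded clustering loop, a synthetic tumor-phantom
    generator for "bottle-neck" and "dual-tail" object shapes, segmentation
    metrics (precision, recall, F-measure, Hausdorff distance, ROC/AUC), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
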