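Package: helmus
Title: Hierarchical Extreme Learning Machines for Breast Ultrasound Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates hierarchical extreme learning machines
    (stacked ELM sparse autoencoders with a random scattering stage and a
    ridge-regularized single-layer ELM decision head) on small binary
    lesion silhouettes derived from breast ultrasound images and their
    ground-truth masks. Includes the mask-guided preprocessing chain
    (binarization, square sizing, block downsampling to 28x28), a seeded
    synthetic lesion-silhouette generator for download-free benchmarking,
    stratified train/test splitting, confusion-matrix evaluation,
    architecture sweeps over layer and hidden-node counts, and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
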