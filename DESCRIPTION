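Package: nutriwalk
Title: Network Propagation and Metric Learning for Food-Based Modulators of Radiotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts bioactive food molecules that modulate radiotherapy
    response by propagating phenotype and molecule protein targets over a
    multiscale protein/biological-function interactome with biased random
    walks with restarts, embedding the resulting diffusion profiles with
    triplet-loss metric learning, and ranking molecules by proximity to the
    phenotype in the learned space. A recipe-optimization module then
    substitutes ingredients using context-embedding nearest neighbours to
    maximize predicted modulator content under culinary, allergy, and
    preference constraints. Includes seeded synthetic-data generators for
    every input the pipeline consumes, with planted signal so each stage's
    recovery behaviour is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
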