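Package: snbda
Title: Bayesian Spatial Network-Based Diffusion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers social transmission of behaviour from diffusion data when
    only the spatial locations of individuals (nests or home bases) are known.
    Builds inter-individual association matrices from the overlap of circular
    zones of influence, fits nested continuous-time hazard models of social
    transmission (time-of-acquisition diffusion analysis) by Markov chain Monte
    Carlo with reversible-jump model discrimination, simulates diffusions on the
    spatial network with the Gillespie algorithm, and provides point-pattern
    exploration (Ripley's K, pair correlation, complete-spatial-randomness
    envelopes) for interaction-radius selection, together with a wave-of-advance
    regression baseline.
License: MIT
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
    optparse,
    withr
Config/testthat/edition: 3
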