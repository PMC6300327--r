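Package: coevoBC
Title: Coupled Eco-Evolutionary Host-Parasitoid Dynamics for Biological Control
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-generation host-parasitoid population dynamics coupled to
    quantitative-trait coevolution of host resistance and parasitoid virulence,
    in the Hochberg-Holt tradition. Provides the two-species simulator, a
    three-species extension in which a second parasitoid is introduced into an
    established system, global sensitivity analysis (Latin hypercube sampling
    with partial rank correlation coefficients and bootstrap confidence
    intervals), additive-genetic-variance ratio sweeps, two-parasitoid
    introduction grids, long-horizon parasitism-rate predictions for two New
    Zealand weevil-parasitoid systems, and a model-versus-field comparison
    pipeline with a beta-binomial synthetic field-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
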