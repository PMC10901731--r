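Package: coopdyn
Title: Evolutionary Dynamics of Continuous Reciprocity Under Repeated
    Interactions and Intergroup Competition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulator for the evolution of cooperation in a
    subdivided (island-model) population whose members play a sequential
    social dilemma with a continuous action space. Heritable strategies
    consist of an initial transfer plus a response function in two, three
    or four dimensions, covering perfect, escalating, de-escalating and
    ambiguous forms of reciprocity. Three scenarios are supported: repeated
    ingroup interactions alone, one-shot play with stochastic contests
    between paired groups, and their combination, in which the two
    mechanisms can interact to produce super-additive levels of
    cooperation. The package provides the full factorial scenario grid,
    seeded replicate runs, an analytic fixed-point oracle for linear
    response functions, strategy-type classification, surplus and
    variance-partition statistics, bootstrap confidence intervals, and a
    decomposition of joint-scenario surplus into repeated-interaction,
    group-competition and super-additive components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
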