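Package: fcbm
Title: Fitness-Corrected Block Models for Synthetic Spatial Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, solving and sampling maximum-entropy
    random-graph ensembles with block-wise mixing and vertex-intrinsic
    fitness (the fitness-corrected block model, an adjustable-density
    generalization of the degree-corrected block model). Provides an exact
    fixed-point solver for the Lagrange-multiplier system defining the edge
    probabilities, closed-form sparse-regime multipliers, analytical
    degree-distribution estimators tied to the chosen fitness distribution,
    Bernoulli graph sampling, and a data-driven spatial instantiation that
    generates age- and geography-stratified synthetic social contact
    networks on a tessellated territory with gravity-style distance decay.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
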