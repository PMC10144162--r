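Package: floralint
Title: Floral Integration, Pollinator Trait Matching, and Phylogenetic
    Piecewise Structural Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking pollinator mouthpart morphology to the
    integration of floral phenotypes across a clade. Implements the
    eigenvalue-variance index of phenotypic integration with its
    small-sample correction and percentile bootstrap, visitation-weighted
    composite proboscis length of a pollinator assemblage, phylogenetic
    generalized least squares under Brownian motion, Pagel's lambda and
    Ornstein-Uhlenbeck correlation structures with maximum-likelihood
    estimation and AIC model comparison, and phylogenetic piecewise
    structural equation models assessed by Shipley's test of d-separation
    (Fisher's C). A synthetic-data generator produces trees, species
    means with a known causal structure, individual flowers and
    pollinator observations with full ground truth for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
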