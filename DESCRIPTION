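Package: stomkin
Title: Unified Modelling of Stomatal Conductance Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stomatal conductance (gs) responses to step
    changes in light intensity across species. Implements four dynamic gs
    response models (empirical t63, exponential, sigmoidal/Gompertz, and the
    two-parameter cumulative-distribution Weibull) with closed-form speed
    metrics (time constant tau, maximum slope Slmax, t63); automated curation
    of gas-exchange time courses (light-step detection, transient-artifact
    stripping, steady-state trimming); hierarchical Bayesian fitting of curve
    sets with shared time constants and per-curve endpoints, with MCMC
    diagnostics and Pareto-smoothed importance-sampling leave-one-out model
    comparison; derivation of species-level kinetic traits and composite
    two-surface (amphistomatous) leaf simulation; comparative statistics
    (standardized major axis regression, Kruskal-Wallis with Dunn post hoc and
    compact letter displays, principal component analysis); exhaustive
    phylogenetic regression model selection over anatomy-kinetics candidate
    models with exact leave-one-out ranking; and a synthetic-data generator
    providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
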