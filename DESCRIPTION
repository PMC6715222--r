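Package: smokesim
Title: Agent-Based Microsimulation of Adolescent Cigarette and E-Cigarette Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based microsimulation of conventional-cigarette and
    e-cigarette use among high-school adolescents. Agents on a static
    scale-free friendship network repeatedly choose among non-use, cigarette
    use, e-cigarette use and dual use by maximising a random utility that
    combines intrinsic taste, habituation, use frequency, and social
    influence from close peers and from population-level prevalence,
    mediated by a dynamic "openness to smoking" attitude and an optional
    one-way "crossover" coupling from e-cigarette exposure to cigarette
    openness. Includes a synthetic-population generator emulating 2011
    US National Youth Tobacco Survey marginals, calibration of utility
    weights to yearly prevalence targets, backward validation against
    95% confidence intervals, and a counterfactual openness-by-crossover
    scenario grid averaged over seeded replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
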