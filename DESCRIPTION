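Package: phoresim
Title: Vertical Transmission Limits for Phoretic Colony Symbionts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for bounding the contribution of vertical (parent-to-
    offspring-colony) transmission to symbiont prevalence in social-insect
    colonies. Implements a deterministic two-class model of infected and
    uninfected incipient and mature colonies with a closed-form equilibrium
    infection prevalence, the estimation chain that parameterises it (Cox
    proportional-hazards fit of incipient-garden survivorship yielding the
    symbiont virulence ratio, exact binomial confidence intervals, and
    field-survey prevalence summaries), a discrete-time stochastic cohort
    simulator used as an independent Monte-Carlo check on the equilibrium,
    and seed-deterministic synthetic-data generators for the survivorship
    experiment and nuptial-flight survey designs the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
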