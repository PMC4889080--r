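Package: rralloc
Title: Resource-Reallocation Analysis of Infant Milestone Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for event-aligned analysis of longitudinal infant
    observation data: detection of milestone initiation ages from session
    count tables, pre-milestone peak and post-milestone rebound extraction,
    two-point event-aligned rate-change coefficients, and the composite
    resource-reallocation (RR) score that integrates changes in symbolic
    play and speech around the transitions to words, complex play and
    walking. Includes a seeded Poisson count-trajectory simulator for
    cohorts with ordered milestone ages, transition-locked frequency dips
    with rebounds, and a tunable coupling between latent RR and
    walking-onset age; plus small-sample inference (Pearson correlations
    with parametric and permutation p-values, paired t contrasts, Cohen's
    kappa) and a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml,
    optparse
Config/testthat/edition: 3
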