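Package: lifetab
Title: Fertility Life Tables and Jackknife Demography for Insect Cohorts
Version: 1.0.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cohort-based fertility life-table analysis for single-pair
    insect rearing studies. Converts individual female records (daily or
    interval egg censuses, longevity, oviposition periods) and per-female
    offspring tallies into age-specific survival (lx) and fecundity (mx)
    schedules, solves the Euler-Lotka equation for the intrinsic rate of
    increase, and derives the finite rate of increase, net reproductive
    rate, and mean generation time. Standard errors come from
    leave-one-female-out jackknife pseudo-values; treatment cells are
    compared with Tukey studentized-range tests on pseudo-values and with
    two-way (cluster x host) analysis of variance on biological traits. A
    calibrated stochastic cohort generator reproduces the design of a
    published Bemisia tabaci MED mating-group study (8 treatment cells,
    30 single-pair families each, 2-day censuses) so the whole pipeline
    is testable without access to raw rearing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
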