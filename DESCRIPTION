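Package: capnovent
Title: In-Silico Crossover Study of Variable Ventilation During Capnoperitoneum
Version: 0.1.0
Authors@R:
    person("Capnovent", "Developers", email = "capnovent@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for crossover animal studies of
    variable versus pressure-controlled ventilation during capnoperitoneum.
    Generates pressure-controlled and variable-ventilation breath plans and
    delivers them on a single-compartment lung model; synthesizes
    multifrequency forced-oscillation recordings and estimates respiratory
    input impedance with constant-phase model fitting (airway resistance and
    inertance, tissue damping and elastance, hysteresivity); computes oxygen
    contents, alveolar oxygen tension, and the modified Berggren shunt
    fraction from blood-gas panels; generates a synthetic crossover cohort
    parameterized from published stage summaries; and reproduces the study
    statistics (two-way repeated-measures ANOVA with sphericity corrections,
    Holm-Sidak post hoc tests, relative-change confidence intervals, and
    Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
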