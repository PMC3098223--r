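Package: lignoflux
Title: Constraint-Based and Kinetic Ensemble Analysis of Monolignol Biosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative flux analysis of the monolignol biosynthesis pathway in
    alfalfa (Medicago sativa) stems. Provides the 24-reaction stoichiometric model
    of the pathway with its three overflow extensions, per-internode flux balance
    analysis of wild-type plants under lignin monomer (H/G/S) proportionality
    constraints, enumeration of alternate optima and selection of a unique
    reference flux distribution, prediction of transgenic flux redistributions by
    minimization of metabolic adjustment (MOMA) under enzyme knockdown
    constraints, developmental trend classification of branch-point flux
    partitioning, and a Monte Carlo ensemble of Michaelis-Menten/Hill kinetic
    branch-point models used to assess whether enzyme kinetics alone can explain
    observed shifts in the S/G lignin ratio. Includes a seeded synthetic-data
    generator emulating the per-line, per-internode observation tables of the
    underlying transgenic study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    quadprog,
    deSolve,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
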