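Package: loxkin
Title: Mechanistic Kinetics of L-Lactate Oxidase Half-Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action modelling and fitting of the two-half-reaction
    (ping-pong) kinetic mechanism of Aerococcus viridans L-lactate oxidase.
    Provides a stiff ODE model of the reductive (substrate binding, FMN
    reduction, pyruvate release) and oxidative (FMN re-oxidation by O2)
    half-reactions, a synthetic stopped-flow and steady-state data
    generator with an instrument model (dead time, sampling, noise),
    exponential and hyperbolic fitting of stopped-flow traces, combined
    ODE-simulation fitting of charge-transfer traces, Michaelis-Menten
    fitting of initial-rate tables, and the closed-form algebra linking
    microscopic rate constants to apparent turnover numbers, K_m for O2,
    and per-step rate-limitation fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
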