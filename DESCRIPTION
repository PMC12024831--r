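Package: clopbbm
Title: Physiologically Based Biopharmaceutics Modeling of Clopidogrel
    Solid Dispersions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic oral-absorption modeling for clopidogrel, a weakly
    basic BCS class II antiplatelet drug with strongly pH-dependent
    solubility. Implements a nine-compartment compartmental absorption and
    transit (ACAT-style) gastrointestinal model coupled to three-compartment
    systemic disposition with hepatic first-pass extraction, pH-dependent
    solubility interpolation and dose-number classification, polydisperse
    shrinking-particle (Noyes-Whitney/Johnson) dissolution, tabulated
    controlled-release profile inputs for solid dispersions, dissolution
    kinetics model fitting (zero-order, first-order, Higuchi,
    Korsmeyer-Peppas, Hixson-Crowell), fold-error validation against
    observed pharmacokinetics, and a generator of reciprocating-cylinder
    (Bio-Dis) pH-gradient dissolution profiles for solid-dispersion
    formulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
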