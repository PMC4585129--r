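Package: aombatch
Title: Energetics, Tracer Accounting and Growth Assessment for Anaerobic
    Methane Oxidation Batch Incubations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for long-term batch incubation studies of sulfate-coupled
    anaerobic oxidation of methane (AOM) in marine sediments. Computes the
    transformed Gibbs free energy of AOM from in-situ concentrations and
    classifies conditions against bioenergetic thresholds; performs
    13CH4-tracer bookkeeping (headspace gas amounts, isotopologue fractions,
    baseline-anchored 13CO2 production, methane-oxidized estimates); derives
    the FeCl2/Na2SO4/FeSO4 amendment doses that hold sulfide and sulfate at
    experimental setpoints, with sulfur mass balance; fits qPCR standard
    curves and quantifies ANME subclade abundances and fold-change growth
    calls with Welch tests and compact letter displays; and generates a fully
    seeded synthetic incubation study (7 conditions in triplicate over 947
    days) so the whole pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
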