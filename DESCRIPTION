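Package: radikin
Title: Two-Step Radical Reaction Energetics and Nonadiabatic Kinetics for
    Nucleobase Photochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-step radical reaction schemes in
    nucleobase photochemistry: species-energy ledgers with zero-point
    corrected relative energies, photon-feasibility gating of homolytic
    cleavage channels under UVA/UVB radiation bands, characterization of
    one-dimensional potential-energy scans (wells, barriers, singlet-triplet
    crossings), and nonadiabatic rate expressions (canonical transition-state
    theory with photon-energy partitioning, semiclassical Marcus intersystem
    crossing rates, and Landau-Zener hopping probabilities). Includes a
    seeded synthetic-curve generator with analytic ground truth for
    validating the scan-analysis machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
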