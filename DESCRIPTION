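Package: antiradical
Title: Conceptual-DFT Antiradical Profiling and Donor-Acceptor Maps
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes vertical ionization potentials and electron affinities
    from neutral/cation/anion total electronic energies, the global
    conceptual-DFT reactivity descriptors (hardness, softness,
    electronegativity, chemical potential, electrophilicity), the
    electro-donating and electro-accepting powers, and the Rd/Ra
    donor-acceptor map used to classify radical-scavenging compounds as
    electron donors or acceptors. Includes gas-versus-implicit-solvent
    comparison, frontier-orbital (HOMO/LUMO) ranking with a consistency
    check against ionization-potential order, DPPH dose-response statistics
    (percent inhibition, IC50 by log-linear interpolation or four-parameter
    logistic fit, descriptor-activity Pearson correlation with residuals),
    and a seeded synthetic-data generator so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
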