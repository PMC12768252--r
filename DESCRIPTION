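Package: guvpore
Title: Electroporation Rupture Kinetics and Pore-Edge Tension of Giant
    Unilamellar Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing electric field-induced rupture of giant
    unilamellar vesicles (GUVs). Maps applied field and vesicle geometry to
    transmembrane voltage and lateral electric tension, computes pore
    nucleation energetics (prepore free energy, critical radius, Arrhenius
    rupture rate), fits single-exponential survival kinetics to right-censored
    per-vesicle rupture times, infers pore-edge (line) tension from rate
    constants measured at multiple tensions, and fits a biphasic model of
    edge tension versus peptide content. Includes a stochastic simulator of
    per-vesicle rupture experiments for validation and power analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
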