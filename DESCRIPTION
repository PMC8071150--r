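Package: protonuq
Title: Dose and Range Uncertainty Budgets for a Preclinical Proton Beamline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic central-axis proton dose engine and uncertainty
    pipeline for a 68 MeV preclinical beamline. Provides relativistic Bethe
    stopping power and CSDA ranges with configurable mean excitation
    energies, sequential transport through the beamline component stack
    (energy degradation, Bohr energy straggling, Highland multiple
    scattering), analytic Bragg curves in water and in heterogeneous voxel
    columns, a synthetic mouse micro-CBCT phantom generator with
    HU-to-material calibration, the plateau dose / R80 range / HI98
    homogeneity metrics with significance classification, and a scenario
    driver that combines per-source range and dose uncertainties in
    quadrature into the study's uncertainty budget.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
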