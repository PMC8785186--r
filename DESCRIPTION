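Package: neaspec
Title: Nuclear Ensemble Photoabsorption Cross-Sections with Quantum Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts absolute photoabsorption cross-sections of small molecules
    with the nuclear ensemble approach (NEA). Ground-state nuclear densities are
    sampled either from the harmonic Wigner distribution of the vibrational
    ground state (with selective mode exclusion) or from classical molecular
    dynamics driven by a colored-noise generalized Langevin quantum thermostat.
    Per-geometry vertical transition tables are broadened into absolute
    cross-sections in cm^2 per molecule, conformer spectra are combined with
    Boltzmann weights, and photolysis rate coefficients are obtained by
    integrating cross-section, quantum yield and actinic flux over wavelength.
    Analytic model potentials and toy chromophores allow end-to-end validation
    without an electronic-structure engine, including the rectilinear-mode
    torsion artifact of harmonic Wigner sampling and its mode-filtering fix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
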