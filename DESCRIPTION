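Package: nanoplume
Title: Atmospheric Dispersion and Deposition of Nanomaterials from Point Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian plume modelling of engineered nanomaterials and other
    depositing aerosols released from a continuous point source. Implements the
    classic Gaussian plume, the Ermak depositing plume, a boundary-layer
    reflection (image source) series with a sign-corrected effective source
    height, and an iterative mass-balance correction enforcing that deposited
    plus suspended mass fractions sum to one at every downwind distance.
    Provides Pasquill stability class dispersion parametrizations (Klug and
    Davidson), size-dependent settling and dry deposition velocities
    (Stokes-Cunningham settling plus a resistance-based canopy collection
    model), ground deposition fluxes, the half-deposited distance x50
    separating local from regional exposure scales, near-field/far-field
    compartment concentrations, long-term soil accumulation (PECsoil) and
    PEC/PNEC risk ratios, plus scenario configuration, parameter sweeps and
    case-study helpers for screening-level exposure assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
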