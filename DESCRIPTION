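Package: lipidorder
Title: Solid-State NMR Lineshape Analysis of Model Membrane Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and analysis of wide-line solid-state NMR
    spectra of multilamellar lipid vesicles. Simulates axially symmetric
    2H quadrupolar and 31P chemical-shielding-anisotropy powder patterns
    (including prolate vesicle deformation and Lorentzian broadening),
    de-Pakes powder spectra into oriented-like spectra by regularized
    non-negative inversion, extracts acyl-chain C-D order parameters and
    thermal order profiles, and iteratively fits multi-component 31P
    spectra of phosphoinositide-rich membranes to recover per-phosphate
    chemical shielding anisotropies. Includes a seeded synthetic-spectrum
    generator for fusogenic nuclear-envelope precursor membrane scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
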