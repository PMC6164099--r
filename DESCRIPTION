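Package: sprshell
Title: Surface Plasmon Resonance Biosensor Modelling with Core-Shell
    Nanoparticle Composites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models angle-interrogated surface plasmon resonance (SPR)
    biosensors in the Kretschmann attenuated-total-reflection geometry.
    Computes the quasi-static effective permittivity of metal-coated
    magnetic core-shell nanoparticles by internal homogenization,
    homogenizes core-shell + biomaterial + water composites with a
    Maxwell-Garnett mixing rule, evaluates p-polarized multilayer
    reflectivity by both a recursive Fresnel formula and a 2x2
    characteristic-matrix method, locates resonance dips with parabolic
    refinement, and derives refractometric sensitivity and enhancement
    metrics from dip shifts. Includes calibration of unprinted
    constituent permittivities from published effective-permittivity
    tables, a scenario fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
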