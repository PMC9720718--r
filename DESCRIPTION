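Package: specens
Title: Nuclear-Ensemble Absorption Spectra from Conformer Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for simulating electronic absorption
    spectra of flexible fluorophores from molecular-dynamics conformer
    ensembles and per-conformer vertical excitation data.  Provides
    trajectory frame handling and sampling schedules, signed dihedral and
    distance geometry, circular statistics for multimodal torsional
    distributions, parsing of quantum-chemistry excited-state output,
    nuclear-ensemble spectrum reconstruction by Gaussian broadening of
    vertical transitions, and static-versus-ensemble and gas-versus-solution
    spectral-shift reports.  A seeded synthetic-data generator emulates the
    coupled torsion/excitation structure of such datasets so every stage is
    testable without molecular dynamics or quantum chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    tidyr,
    stats,
    utils,
    ggplot2,
    generics,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
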