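Package: nanocd
Title: Binding Analysis and Boltzmann-Weighted Circular-Dichroism Sensing for
    Ligand-Protected Gold Nanoclusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis pipeline for chiral gold-nanocluster
    biosensing. Computes contact-number (NOC) series and the adsorption
    probability statistic from molecular-dynamics trajectories, center-of-mass
    distances, hydrogen-bond and interaction-energy diagnostics, and
    multi-analyte bound counts under periodic boundary conditions; selects
    representative conformations by principal-component analysis, a
    two-dimensional free-energy landscape, and RMSD-based geometric
    clustering; and forms Boltzmann-weighted ensemble-average and
    hybrid-minus-bare difference circular-dichroism spectra with
    binding-detectability and enantiodiscrimination scores. Includes
    ground-truth-known synthetic generators (two-state adsorption kinetics,
    conformational basins, Gaussian-band CD ensembles) for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
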