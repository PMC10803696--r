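Package: pbrpk
Title: Physiologically Based Radiopharmacokinetic Modeling for Radiopharmaceutical Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scalable reaction-graph notation for physiologically based
    radiopharmacokinetic (PBRPK) compartmental models of radiopharmaceutical
    therapy, with a stiff ODE simulation engine supporting multi-bolus
    injection schedules, a self-dose dosimetry layer (time-integrated
    activity, absorbed dose, blood residence time), and three simulation
    studies over virtual-patient grids: hot/cold ligand competition
    summarized by iso-dose twist angles, injection fractionation summarized
    by the maximum relative dose change (MRDC), and albumin-binding affinity
    sweeps summarized by blood residence time and the tumor/organ-at-risk
    enhancement factor. Models exchange through SBML Level 3 Version 2 core.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
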