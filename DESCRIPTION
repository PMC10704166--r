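Package: tdcsflow
Title: Current-Flow Modelling of Transcranial Direct Current Stimulation
    with Idealized and As-Placed Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the electric field and current density delivered by
    transcranial direct current stimulation (tDCS) in voxelized
    multi-compartment head phantoms with parameterized brain atrophy.
    Places idealized ("artificial") and perturbed as-placed ("real")
    pad-plus-gel electrode montages on the scalp, solves the quasi-static
    volume-conduction problem div(sigma grad phi) = 0 with Neumann current
    injection by a finite-volume method, and reduces the fields to region-
    of-interest median current densities, paired percent differences,
    electrode geometry metrics, voxelwise paired t-maps, and regressions of
    dose against electrode properties and brain volume ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
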