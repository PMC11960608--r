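Package: relpatlak
Title: Total-Body Parametric PET Imaging with the Relative Patlak Plot
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Voxel-wise parametric imaging of the FDG net influx rate (Ki)
    from short late-time dynamic PET data using the relative Patlak plot,
    which needs the plasma input function only from the equilibrium time t*
    onward. Includes a self-supervised deep-kernel denoiser for the noisy
    short-scan parametric images, a conventional-kernel baseline, a
    total-body dynamic PET phantom simulator with two-tissue irreversible
    FDG kinetics and a Feng-type arterial input, and the quantification and
    agreement analyses (global scaling factor, SUV ratio, contrast ratios,
    Bland-Altman, healthy-cohort calibration, population-based input
    function) used to validate the method.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
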