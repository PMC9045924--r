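Package: desmokeR
Title: Polarization-Difference Smoke Removal for Surgical Imaging
Version: 0.1.0
Authors@R:
    person("desmokeR", "Maintainers", email = "maintainers@desmoker.invalid",
           role = c("aut", "cre"))
Description: Tools for removing electrocautery smoke from surgical images
    using polarization-difference imaging. Implements Mie scattering
    calculations for smoke particles (single-size and polydisperse), a
    Stokes-vector polarized Monte Carlo simulator of backscattering from a
    smoke layer over tissue, a forward degradation model that turns
    smoke-free polarimetric scenes into synthetic smoky test data with
    exact ground truth, the polarization-difference desmoking pipeline
    with haze-line airlight estimation and per-colour-channel transmission
    maps, and a polarimetric/colorimetric evaluation suite (degree of
    polarization, PSNR, SSIM, CIEDE2000). Includes a command-line
    interface and a dependency-free PNG reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
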