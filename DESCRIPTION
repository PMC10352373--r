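Package: usfocus
Title: Simulation and Imaging Analysis of Ultrasound-Shaped Light Focusing in Turbid Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models light focusing inside scattering media by an
    ultrasound-induced gradient-index channel. A resonant cylindrical
    cavity imprints a Bessel-profile refractive-index modulation
    n(r) = n0 + nA*J0(k r)*cos(wt) on the medium; the package propagates
    light through it with a split-step paraxial beam propagation method
    (wave optics) and a 2D photon-packet Monte Carlo transport engine
    (Henyey-Greenstein scattering, continuous eikonal ray bending,
    Fresnel side walls), and analyses the results: beam width and
    focusing-contrast metrics, Beer-Lambert attenuation fits, slanted-edge
    MTF resolution, and a synthetic point-by-point laser-scanning imaging
    model with knife-edge and USAF-1951 three-bar targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
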