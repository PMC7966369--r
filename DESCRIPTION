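Package: photokin
Title: Wavelength-Resolved Simulation of Photochemical Reaction Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the time-dependent conversion and wavelength-dependent
    selectivity of photochemical ligation reactions driven by LEDs or pulsed
    lasers. Implements wavelength-gridded spectra with energy-to-photon
    conversion, segmented Beer-Lambert light attenuation with competitive
    absorption, a wavelength- and concentration-dependent reaction quantum
    yield surface fitted to monochromatic anchor measurements, an iterative
    one-second time-stepping engine with ideal mixing and light-attenuation
    maps, a lambda-orthogonality selectivity scan for competing
    photoreactions, and inverse estimation of quantum yields from observed
    conversions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
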