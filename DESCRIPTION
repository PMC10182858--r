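Package: dermaspec
Title: Spatially Resolved Diffuse Reflectance Spectroscopy of Layered Skin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward modeling and inversion of spatially resolved diffuse
    reflectance spectra of skin in the 900-1075 nm range. Provides a Monte
    Carlo photon-packet transport engine for plane-parallel layered media
    with white-Monte-Carlo pathlength rescaling, a k-nearest-neighbour
    reflectance lookup table over absorption and layer-thickness grids,
    decomposition of optical-density spectra into water and lipid band
    amplitudes, and regularized regression models that recover dermal water
    content, dermal thickness and hypodermal thickness from multi-distance
    measurements, together with seeded generators for synthetic cohorts and
    edema timecourses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
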