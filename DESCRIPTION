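Package: mcbacksim
Title: Monte Carlo Simulation of Laser-Induced Diffuse Reflectance
    (Backscattering) on Turbid Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of photon transport in a semi-infinite
    homogeneous turbid medium, producing the radial intensity profile of
    diffusely reflected (backscattered) light on the surface as seen by a
    camera mounted on the surface normal. Photons are launched at an
    oblique incident angle with Snell refraction and elliptic distortion
    of the beam footprint, propagated with exponential free paths and
    Henyey-Greenstein scattering, partially reflected at the boundary by
    Fresnel's equations, and the escaping flux is weighted by a Lambertian
    (cosine of exit angle) factor. A closed-form dipole diffusion-theory
    reflectance model and profile comparison statistics (Pearson
    correlation, RMSE) are included for validation, together with a JSON
    configuration format and a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
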