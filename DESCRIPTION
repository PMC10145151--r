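Package: chromodr
Title: Response-Surface Modeling and Method Operable Design Regions for
    Gradient Liquid Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Analytical Quality by Design (AQbD) development of
    gradient liquid chromatography methods. Builds face-centered central
    composite designs over critical method parameters (flow rate, gradient
    time, column temperature), fits transformed reduced quadratic response
    surface models of critical method attributes (peak-boundary retention
    times and the retention factor of the last-eluting analyte) with PRESS,
    lack-of-fit and Box-Cox diagnostics, and computes the Method Operable
    Design Region (MODR) by Monte Carlo propagation of coefficient
    uncertainty over a discretized factor grid. Ships the 18-run fatty-acid
    separation study used throughout the documentation, together with a
    seeded synthetic-data generator for end-to-end testing.
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
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
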