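Package: gwmap
Title: Neural-Network-Informed Spatial Interpolation for Groundwater
    Quality Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping groundwater physicochemical parameters and
    heavy-metal concentrations from sparse well surveys. Implements nine
    families of spatial interpolation (inverse distance weighting, global
    and local polynomials, radial basis functions, kernel smoothing with
    barriers, ordinary/universal/empirical Bayesian kriging), a
    particle-swarm-initialised Levenberg-Marquardt feedforward network
    that densifies a survey with pseudo-stations predicted from cheap
    covariates, leave-one-out cross-validation with MAE/Pearson-R method
    selection, descriptive and multivariate screening against
    drinking-water guidelines, and seeded synthetic survey generators for
    end-to-end testing.
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
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
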