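# Seeded synthetic surveys with the statistical structure the method
# assumes: a spatially autocorrelated latent field, covariates linearly
# linked to it, and measurement noise. Everything is bit-reproducible
# given its seed.

#' The 36 Marinduque sampling stations
#'
#' Station ids, barangay/municipality, WGS84 coordinates and elevation of
#' the groundwater survey wells, projected to UTM zone 51N on request.
#'
#' @param project Project to UTM 51N (default TRUE).
#' @return Survey tibble of 36 stations (coordinates only, no values).
#' @export
marinduque_stations <- function(project = TRUE) {
  path <- system.file("extdata", "marinduque_stations.csv",
                      package = "gwmap", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  s <- as_survey(df)
  if (project) s <- project_utm(s, zone = 51)
  s
}

#' Synthetic field specification
#'
#' Describes the generating model of [make_survey()]: a latent Gaussian
#' random field with the given variogram and mean, covariates obtained as
#' linear maps of the latent field plus independent noise, and
#' measurement noise on the target.
#'
#' @param vm Latent-field `variogram_model` (default spherical with
#'   range 10 km, partial sill 1, nugget 0.05 — island-scale structure).
#' @param mean Mean level of the latent field.
#' @param link Named list of covariate links, each
#'   `list(intercept, slope, noise_sd)`: covariate =
#'   `intercept + slope * latent + N(0, noise_sd^2)`. Default links for
#'   temp/pH/EC/TDS give target-covariate correlations around 0.85-0.95,
#'   mirroring the near-deterministic covariate-target relationships a
#'   well-trained network presumes.
#' @param noise_sd Measurement noise sd on the target (default 0.05).
#' @param nonlinear Apply a monotone nonlinearity (`sinh(z)/1.2`) to the
#'   latent field before linking covariates (exercises the network's
#'   advantage over linear drift; default FALSE).
#' @return A `field_spec`.
#' @export
field_spec <- function(vm = variogram_model("spherical", nugget = 0.05,
                                            psill = 1, range = 10000),
                       mean = 0,
                       link = default_links(),
                       noise_sd = 0.05,
                       nonlinear = FALSE) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(vm = vm, mean = mean, link = link, noise_sd = noise_sd,
                 nonlinear = nonlinear),
            class = "field_spec")
}

default_links <- function() {
  list(
    temp = list(intercept = 36.8, slope = 4.0, noise_sd = 1.5),
    pH = list(intercept = 7.0, slope = -0.5, noise_sd = 0.2),
    EC = list(intercept = 935, slope = 500, noise_sd = 150),
    TDS = list(intercept = 373, slope = 120, noise_sd = 50)
  )
}

#' Simulate a Gaussian random field at given points
#'
#' Exact (dense Cholesky) multivariate-normal draw with covariance
#' `C(h) = sill - gamma(h)`; capped at 2500 points.
#'
#' @param points Two-column matrix or data frame of coordinates (meters).
#' @param vm A bounded `variogram_model` (not power).
#' @param seed Integer seed.
#' @param mean Mean level (default 0).
#' @return Numeric vector of field values.
#' @export
gaussian_random_field <- function(points, vm, seed = 1, mean = 0) {
  tm <- as_target_matrix(points)
  if (nrow(tm) > 2500) abort("dense simulation capped at 2500 points")
  withr::local_seed(seed)
  mean + grf_draw(tm[, 1], tm[, 2], vm)
}

#' Generate a synthetic survey (and its truth)
#'
#' Draws the latent field jointly at the stations and any auxiliary
#' sites, adds measurement noise to the target at the stations, and
#' derives covariates from the latent field through the linear links (so
#' the network has recoverable signal). Auxiliary sites get covariates
#' and the true target for scoring, but no observed target.
#'
#' @param spec A [field_spec()].
#' @param stations Survey tibble of station locations (default
#'   [marinduque_stations()]).
#' @param aux_points Optional matrix/tibble of auxiliary coordinates.
#' @param parameter Name of the target column (default `"Cd"`).
#' @param season Season tag for the generated survey.
#' @param seed Integer seed.
#' @return List: `survey` (stations with target + covariates), `aux`
#'   (auxiliary tibble with x, y, covariates, `truth`), `truth` (latent +
#'   mean at the stations).
#' @export
make_survey <- function(spec = field_spec(), stations = marinduque_stations(),
                        aux_points = NULL, parameter = "Cd",
                        season = "dry", seed = 1) {
  withr::local_seed(seed)
  n_st <- nrow(stations)
  am <- if (!is.null(aux_points)) as_target_matrix(aux_points) else
    matrix(0, 0, 2)
  allx <- c(stations$x, am[, 1]); ally <- c(stations$y, am[, 2])
  latent <- spec$mean + grf_draw(allx, ally, spec$vm)
  glat <- if (spec$nonlinear) sinh(latent - spec$mean) / 1.2 + spec$mean
          else latent
  s <- stations
  s$season <- season
  s[[parameter]] <- latent[seq_len(n_st)] +
    rnorm(n_st, 0, spec$noise_sd)
  for (cv in names(spec$link)) {
    lk <- spec$link[[cv]]
    s[[cv]] <- lk$intercept + lk$slope * (glat[seq_len(n_st)] - spec$mean) +
      rnorm(n_st, 0, lk$noise_sd)
  }
  aux <- NULL
  if (nrow(am) > 0) {
    aux <- tibble(x = am[, 1], y = am[, 2])
    ia <- n_st + seq_len(nrow(am))
    for (cv in names(spec$link)) {
      lk <- spec$link[[cv]]
      aux[[cv]] <- lk$intercept + lk$slope * (glat[ia] - spec$mean) +
        rnorm(nrow(am), 0, lk$noise_sd)
    }
    aux$truth <- latent[ia]
  }
  list(survey = s, aux = aux, truth = latent[seq_len(n_st)])
}
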