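# Empirical semivariogram estimation and weighted-least-squares model
# fitting for the kriging interpolators.

#' Variogram model
#'
#' Parametric semivariogram `gamma(h) = nugget + psill * g(h/range)` with
#' `g` the unit correlation complement of the chosen family:
#' spherical (`1.5u - 0.5u^3` up to the range, then 1), exponential
#' (`1 - exp(-u)`), gaussian (`1 - exp(-u^2)`), or the unbounded power
#' model `nugget + psill * h^range_exponent` (here `psill` is the slope
#' and `range` the exponent in (0, 2)).
#'
#' @param family `"spherical"`, `"exponential"`, `"gaussian"` or `"power"`.
#' @param nugget Nugget variance (>= 0).
#' @param psill Partial sill (>= 0); slope for the power model.
#' @param range Range parameter in meters (> 0); exponent for power.
#' @return A `variogram_model` object.
#' @export
variogram_model <- function(family = c("spherical", "exponential",
                                       "gaussian", "power"),
                            nugget = 0, psill = 1, range = 1) {
  family <- match.arg(family)
  if (nugget < 0 || psill < 0) abort("nugget and psill must be >= 0")
  if (range <= 0) abort("range must be > 0")
  if (family == "power" && range >= 2) abort("power exponent must be in (0, 2)")
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, psill %.4g, range %.4g\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' @export
tidy.variogram_model <- function(x, ...) {
  tibble(family = x$family, nugget = x$nugget, psill = x$psill,
         range = x$range, sill = x$nugget + x$psill,
         wsse = x$wsse %||% NA_real_)
}

#' Evaluate a semivariogram
#'
#' @param vm A `variogram_model`.
#' @param h Lag distances (meters, >= 0).
#' @return `gamma(h)`; `gamma(0) = 0` by convention (the nugget is the
#'   limit from above).
#' @export
vgm_eval <- function(vm, h) {
  u <- h / vm$range
  g <- switch(vm$family,
    spherical = ifelse(u < 1, 1.5 * u - 0.5 * u^3, 1),
    exponential = 1 - exp(-u),
    gaussian = 1 - exp(-u^2),
    power = NULL)
  out <- if (vm$family == "power") vm$nugget + vm$psill * h^vm$range
         else vm$nugget + vm$psill * g
  out[h == 0] <- 0
  out
}

# covariance C(h) = sill - gamma(h) for bounded families
vgm_cov <- function(vm, D) {
  if (vm$family == "power") {
    abort("power model has no sill; cannot form a covariance")
  }
  sill <- vm$nugget + vm$psill
  C <- sill - vgm_eval(vm, D)
  C
}

#' Empirical (Matheron) semivariogram
#'
#' Half the mean squared difference of all station pairs, binned by
#' separation distance.
#'
#' @param s Survey tibble with projected coordinates.
#' @param parameter Parameter name.
#' @param n_lags Number of equal-width distance bins (default 12).
#' @param max_lag Largest lag considered (default half the maximum
#'   pairwise distance).
#' @return A tibble of class `empirical_variogram` with `lag` (bin
#'   center), `gamma`, `n_pairs`, and attribute `max_lag`.
#' @export
empirical_variogram <- function(s, parameter, n_lags = 12, max_lag = NULL) {
  pts <- survey_points(s, parameter)
  if (length(pts$z) < 10) abort("need at least 10 stations")
  empirical_variogram_xyz(pts$x, pts$y, pts$z, n_lags, max_lag)
}

empirical_variogram_xyz <- function(x, y, z, n_lags = 12, max_lag = NULL) {
  pts <- list(x = x, y = y, z = z)
  D <- pair_dist(pts$x, pts$y, pts$x, pts$y)
  iu <- which(upper.tri(D))
  d <- D[iu]
  dz2 <- (outer(pts$z, pts$z, "-")^2)[iu]
  max_lag <- max_lag %||% (max(d) / 2)
  keep <- d <= max_lag & d > 0
  if (!any(keep)) abort("all station pairs are beyond max_lag")
  width <- max_lag / n_lags
  bin <- pmin(ceiling(d[keep] / width), n_lags)  # bins are (lo, hi]
  gamma <- vapply(seq_len(n_lags), function(b) {
    if (any(bin == b)) mean(dz2[keep][bin == b]) / 2 else NA_real_
  }, 0)
  np <- vapply(seq_len(n_lags), function(b) sum(bin == b), 0L)
  out <- tibble(lag = (seq_len(n_lags) - 0.5) * width, gamma = gamma,
                n_pairs = np)
  attr(out, "max_lag") <- max_lag
  class(out) <- c("empirical_variogram", class(out))
  out
}

#' Plot an empirical variogram
#' @param object An `empirical_variogram`.
#' @param model Optional fitted `variogram_model` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::labs(x = "lag (m)", y = "semivariance") +
    ggplot2::scale_size_area()
  if (!is.null(model)) {
    h <- seq(0, max(object$lag), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(lag = h, gamma = vgm_eval(model, h)),
      ggplot2::aes(.data$lag, .data$gamma), colour = "steelblue")
  }
  p
}

# given range, solve (nugget, psill) >= 0 by weighted linear least squares
wls_np <- function(gobs, gbasis, w) {
  X <- cbind(1, gbasis)
  A <- crossprod(X * sqrt(w)); b <- crossprod(X, w * gobs)
  sol <- tryCatch(drop(solve(A, b)), error = function(e) c(0, 0))
  if (sol[1] < 0) {
    sol[1] <- 0
    sol[2] <- sum(w * gbasis * gobs) / max(sum(w * gbasis^2), 1e-300)
  }
  if (sol[2] < 0) {
    sol[2] <- 0
    sol[1] <- max(sum(w * gobs) / sum(w), 0)
  }
  unname(sol)
}

fit_one_family <- function(ev, family, max_lag) {
  use <- !is.na(ev$gamma) & ev$n_pairs > 0
  lag <- ev$lag[use]; gobs <- ev$gamma[use]; np <- ev$n_pairs[use]
  unit <- function(range) {
    vm <- variogram_model(family, 0, 1, range)
    vgm_eval(vm, lag)
  }
  obj <- function(range) {
    gb <- unit(range)
    w <- np
    # Cressie weights N/gamma_model^2, iterated from N-weights
    for (it in 1:3) {
      cf <- wls_np(gobs, gb, w)
      gm <- cf[1] + cf[2] * gb
      w <- np / pmax(gm, 1e-12)^2
    }
    cf <- wls_np(gobs, gb, w)
    gm <- cf[1] + cf[2] * gb
    sum(w * (gobs - gm)^2)
  }
  opt <- optimize(obj, interval = c(max_lag * 1e-3, 2 * max_lag))
  range <- opt$minimum
  gb <- unit(range)
  w <- np
  for (it in 1:3) {
    cf <- wls_np(gobs, gb, w)
    w <- np / pmax(cf[1] + cf[2] * gb, 1e-12)^2
  }
  cf <- wls_np(gobs, gb, w)
  vm <- variogram_model(family, nugget = cf[1], psill = cf[2], range = range)
  vm$wsse <- sum(w * (gobs - (cf[1] + cf[2] * gb))^2)
  vm
}

#' Fit a variogram model by weighted least squares
#'
#' For each candidate family the range is profiled by 1-D optimisation
#' with nugget and partial sill solved by non-negative weighted linear
#' least squares under Cressie weights `N(h)/gamma_model(h)^2`; the family
#' with the smallest weighted SSE wins.
#'
#' @param ev An `empirical_variogram`.
#' @param families Candidate families (default spherical, exponential,
#'   gaussian).
#' @return The winning `variogram_model` (with `$wsse`).
#' @export
fit_variogram <- function(ev, families = c("spherical", "exponential",
                                           "gaussian")) {
  use <- !is.na(ev$gamma) & ev$n_pairs > 0
  if (sum(use) < 4) abort("need at least 4 non-empty lag bins")
  max_lag <- attr(ev, "max_lag") %||% max(ev$lag)
  fits <- purrr::map(families, function(fam) {
    tryCatch(fit_one_family(ev, fam, max_lag), error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("variogram fitting failed for every family")
  fits[[which.min(purrr::map_dbl(fits, "wsse"))]]
}
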