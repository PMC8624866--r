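#' Interpolator specification
#'
#' A method name plus its parameters, dispatchable by [predict_points()]
#' and [predict_grid()]. Defaults: IDW power 2 with 15 neighbours; GPI
#' degree 1; LPI degree 1 with bandwidth half the survey diagonal; KS
#' ridge `delta = 1e-3`; RBF thin-plate spline; kriging methods fit their
#' variogram from the data unless `vm` is supplied; EBK ensemble size
#' `K = 100` with seed 1.
#'
#' @param method One of `"idw"`, `"gpi"`, `"lpi"`, `"ks"`, `"rbf"`,
#'   `"ok"`, `"uk"`, `"ebk"`.
#' @param ... Method parameters (see the predictor functions).
#' @return An `interp_spec`.
#' @export
interp_spec <- function(method = c("idw", "gpi", "lpi", "ks", "rbf",
                                   "ok", "uk", "ebk"), ...) {
  method <- match.arg(method)
  params <- list(...)
  known <- switch(method,
    idw = c("p", "k"),
    gpi = c("degree"),
    lpi = c("degree", "bandwidth", "delta"),
    ks = c("bandwidth", "delta", "barriers"),
    rbf = c("kernel", "eps", "dedupe_tol"),
    ok = c("vm", "families", "n_lags", "exact", "dedupe_tol"),
    uk = c("vm", "families", "n_lags", "drift", "exact", "dedupe_tol"),
    ebk = c("vm", "families", "n_lags", "K", "subset_size", "seed",
            "exact", "dedupe_tol"))
  unknown <- setdiff(names(params), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s) for method '", method, "': ",
                 paste(unknown, collapse = ", ")))
  }
  structure(list(method = method, params = params), class = "interp_spec")
}

#' @export
print.interp_spec <- function(x, ...) {
  ps <- if (length(x$params) == 0) "defaults" else
    paste(names(x$params), collapse = ", ")
  cat(sprintf("<interp_spec> %s (%s)\n", x$method, ps))
  invisible(x)
}

fitted_vm <- function(spec, s, parameter) {
  p <- spec$params
  if (!is.null(p$vm)) return(p$vm)
  ev <- empirical_variogram(s, parameter, n_lags = p$n_lags %||% 12)
  fit_variogram(ev, p$families %||% c("spherical", "exponential", "gaussian"))
}

#' Predict at arbitrary locations with any interpolator
#'
#' @param spec An [interp_spec()].
#' @param s Survey tibble with projected coordinates.
#' @param parameter Parameter name.
#' @param targets Prediction locations.
#' @return Numeric vector of predictions (kriging variances are available
#'   from the method-specific functions).
#' @export
predict_points <- function(spec, s, parameter, targets) {
  p <- spec$params
  switch(spec$method,
    idw = idw_predict(s, parameter, targets, p = p$p %||% 2,
                      k = p$k %||% 15),
    gpi = gpi_fit_predict(s, parameter, targets, degree = p$degree %||% 1),
    lpi = lpi_predict(s, parameter, targets, degree = p$degree %||% 1,
                      bandwidth = p$bandwidth, delta = p$delta %||% 0),
    ks = ks_predict(s, parameter, targets, bandwidth = p$bandwidth,
                    delta = p$delta %||% 1e-3, barriers = p$barriers),
    rbf = rbf_fit_predict(s, parameter, targets,
                          kernel = p$kernel %||% "thin_plate_spline",
                          eps = p$eps, dedupe_tol = p$dedupe_tol %||% 10),
    ok = ok_predict(s, parameter, fitted_vm(spec, s, parameter), targets,
                    exact = p$exact %||% TRUE,
                    dedupe_tol = p$dedupe_tol %||% 10)$pred,
    uk = uk_predict(s, parameter, fitted_vm(spec, s, parameter), targets,
                    drift = p$drift %||% "linear",
                    exact = p$exact %||% TRUE,
                    dedupe_tol = p$dedupe_tol %||% 10)$pred,
    ebk = ebk_predict(s, parameter, targets, K = p$K %||% 100,
                      subset_size = p$subset_size %||% 50,
                      seed = p$seed %||% 1,
                      families = p$families %||% c("spherical", "exponential",
                                                   "gaussian"),
                      n_lags = p$n_lags %||% 12,
                      exact = p$exact %||% TRUE,
                      dedupe_tol = p$dedupe_tol %||% 10)$pred)
}

#' Predict every cell of a grid
#'
#' @inheritParams predict_points
#' @param grid A `pred_grid` (e.g. from [make_grid()]).
#' @return The grid with `values` filled (and `variance` for kriging
#'   methods); cells where the method declines stay `nodata`.
#' @export
predict_grid <- function(spec, s, parameter, grid) {
  cc <- grid_centers(grid)
  tm <- cbind(cc$x, cc$y)
  vari <- NULL
  if (spec$method %in% c("ok", "uk", "ebk")) {
    p <- spec$params
    res <- switch(spec$method,
      ok = ok_predict(s, parameter, fitted_vm(spec, s, parameter), tm,
                      exact = p$exact %||% TRUE,
                      dedupe_tol = p$dedupe_tol %||% 10),
      uk = uk_predict(s, parameter, fitted_vm(spec, s, parameter), tm,
                      drift = p$drift %||% "linear",
                      exact = p$exact %||% TRUE,
                      dedupe_tol = p$dedupe_tol %||% 10),
      ebk = ebk_predict(s, parameter, tm, K = p$K %||% 100,
                        subset_size = p$subset_size %||% 50,
                        seed = p$seed %||% 1,
                        families = p$families %||% c("spherical",
                                                     "exponential",
                                                     "gaussian"),
                        n_lags = p$n_lags %||% 12,
                        exact = p$exact %||% TRUE,
                        dedupe_tol = p$dedupe_tol %||% 10))
    pred <- res$pred
    vari <- res$var
  } else {
    pred <- predict_points(spec, s, parameter, tm)
  }
  pred[!is.finite(pred)] <- grid$nodata
  grid$values <- matrix(pred, grid$nrows, grid$ncols, byrow = TRUE)
  if (!is.null(vari)) {
    grid$variance <- matrix(vari, grid$nrows, grid$ncols, byrow = TRUE)
  }
  grid
}
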