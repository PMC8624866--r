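# The headline method: a PSO-initialised network learns the target from
# cheap covariates (+ location) at measured stations, predicts it at
# auxiliary sites, and the interpolator runs on the densified survey.

#' Hybrid densification configuration
#'
#' @param target Parameter the network predicts.
#' @param covariates Network inputs: subset of
#'   `c("x", "y", "temp", "pH", "EC", "TDS")`, excluding the target.
#'   Default: location plus all four physicochemical covariates for
#'   heavy-metal targets; location only for physicochemical targets
#'   (their natural covariates would be their own siblings).
#' @param aux_sites Auxiliary sites as a tibble with `x`, `y` and every
#'   non-location covariate; or `NULL` to subsample `n_aux` cells of a
#'   prediction grid (only possible when covariates are location-only).
#' @param n_aux Number of auxiliary sites when subsampling (default 100).
#' @param n_hidden Hidden units of the network (default 10).
#' @param pso A [pso_config()].
#' @param partition_seed Seed for the 70/15/15 partition.
#' @param lambda_pseudo Observation weight in (0, 1] given to
#'   pseudo-stations by weight-aware interpolators (LPI/KS); kriging
#'   treats pseudo-stations as ordinary data.
#' @param lm_max_iter Levenberg-Marquardt iteration cap (default 200).
#' @return A `hybrid_config`.
#' @export
hybrid_config <- function(target, covariates = NULL, aux_sites = NULL,
                          n_aux = 100, n_hidden = 10, pso = pso_config(),
                          partition_seed = 1, lambda_pseudo = 1,
                          lm_max_iter = 200) {
  covariates <- covariates %||%
    if (target %in% c("temp", "pH", "EC", "TDS")) c("x", "y")
    else c("x", "y", "temp", "pH", "EC", "TDS")
  if (target %in% covariates) abort("target must not be among the covariates")
  allowed <- c("x", "y", "temp", "pH", "EC", "TDS")
  bad <- setdiff(covariates, allowed)
  if (length(bad) > 0) {
    abort(paste0("unsupported covariate(s): ", paste(bad, collapse = ", ")))
  }
  if (lambda_pseudo <= 0 || lambda_pseudo > 1) {
    abort("lambda_pseudo must be in (0, 1]")
  }
  structure(list(target = target, covariates = covariates,
                 aux_sites = aux_sites, n_aux = n_aux, n_hidden = n_hidden,
                 pso = pso, partition_seed = partition_seed,
                 lambda_pseudo = lambda_pseudo, lm_max_iter = lm_max_iter),
            class = "hybrid_config")
}

covariate_matrix <- function(df, covariates) {
  cols <- lapply(covariates, function(cv) df[[cv]])
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

# train the covariates -> target network on the measured stations
nn_fit_for <- function(s, cfg) {
  meas <- measured_stations(s)
  need <- c(cfg$target, setdiff(cfg$covariates, c("x", "y")))
  keep <- rowSums(is.na(as.matrix(meas[need]))) == 0
  meas <- meas[keep, ]
  if (nrow(meas) < 7) abort("too few complete stations to train the network")
  X <- covariate_matrix(meas, cfg$covariates)
  y <- meas[[cfg$target]]
  part <- partition_data(nrow(meas), seed = cfg$partition_seed)
  train_nn_pso(X, y, part, n_hidden = cfg$n_hidden, cfg = cfg$pso,
               max_iter = cfg$lm_max_iter)
}

resolve_aux_sites <- function(s, cfg) {
  if (!is.null(cfg$aux_sites)) {
    aux <- as_tibble(cfg$aux_sites)
    need <- setdiff(cfg$covariates, c("x", "y"))
    have <- vapply(need, function(cv) cv %in% names(aux), TRUE)
    if (!all(have)) {
      abort(paste0("auxiliary sites lack covariate(s): ",
                   paste(need[!have], collapse = ", ")))
    }
    miss <- rowSums(is.na(as.matrix(aux[c("x", "y", need)]))) > 0
    if (any(miss)) {
      warn(paste0(sum(miss), " auxiliary site(s) missing a covariate; skipped"))
      aux <- aux[!miss, ]
    }
    if (nrow(aux) == 0) abort("every auxiliary site was skipped")
    return(aux)
  }
  if (length(setdiff(cfg$covariates, c("x", "y"))) > 0) {
    abort(paste0("auxiliary sites must be provided when covariates are not ",
                 "location-only (covariate values are needed there)"))
  }
  g <- make_grid(measured_stations(s), cellsize = grid_cell_for(s))
  cc <- grid_centers(g)
  step <- max(1, floor(nrow(cc) / cfg$n_aux))
  cc[seq(1, nrow(cc), by = step)[seq_len(min(cfg$n_aux, nrow(cc)))],
     c("x", "y")]
}

grid_cell_for <- function(s) {
  m <- measured_stations(s)
  max(diff(range(m$x)), diff(range(m$y))) / 40
}

#' Densify a survey with network-predicted pseudo-stations
#'
#' Trains the covariates-to-target network on the measured stations
#' ([train_nn_pso()]), predicts the target at the auxiliary sites, and
#' appends those sites as pseudo-stations (`is_pseudo = TRUE`, carrying
#' an `obs_weight` of `lambda_pseudo`). With zero auxiliary sites the
#' survey is returned unchanged. Deterministic given the seeds in `cfg`.
#'
#' @param s Survey tibble with projected coordinates.
#' @param cfg A [hybrid_config()].
#' @param fit Optional pre-trained `mlp_fit` (fast mode); default retrains.
#' @return The survey plus pseudo-stations.
#' @export
augment_with_nn <- function(s, cfg, fit = NULL) {
  if (cfg$n_aux == 0) return(s)
  aux <- resolve_aux_sites(s, cfg)
  if (is.null(aux) || nrow(aux) == 0) return(s)
  fit <- fit %||% nn_fit_for(s, cfg)
  Xa <- covariate_matrix(aux, cfg$covariates)
  zhat <- mlp_forward(fit$model, Xa)
  pseudo <- tibble(
    station_id = paste0("PSEUDO", seq_len(nrow(aux))),
    lon = NA_real_, lat = NA_real_,
    x = aux$x, y = aux$y,
    season = s$season[1], is_pseudo = TRUE
  )
  pseudo[[cfg$target]] <- zhat
  for (cv in setdiff(cfg$covariates, c("x", "y"))) pseudo[[cv]] <- aux[[cv]]
  pseudo$obs_weight <- cfg$lambda_pseudo
  if (!"obs_weight" %in% names(s)) s$obs_weight <- 1
  out <- dplyr::bind_rows(s, pseudo)
  class(out) <- class(s)
  attr(out, "nn_fit") <- fit
  out
}

#' Interpolate after network densification
#'
#' [augment_with_nn()] then [predict_grid()] on the augmented survey.
#' Pseudo-stations enter weight-aware interpolators (LPI/KS) with weight
#' `lambda_pseudo` and other interpolators as ordinary points.
#'
#' @param spec An [interp_spec()].
#' @param s Survey tibble.
#' @param cfg A [hybrid_config()].
#' @param grid A `pred_grid`.
#' @return The predicted grid.
#' @export
hybrid_interpolate <- function(spec, s, cfg, grid) {
  predict_grid(spec, augment_with_nn(s, cfg), cfg$target, grid)
}

#' Compare interpolators with and without densification
#'
#' Runs [loocv()] for every requested method, plain and (optionally)
#' hybrid, and selects the governing method by lowest MAE (ties broken by
#' highest R).
#'
#' @param s Survey tibble.
#' @param parameter Parameter name.
#' @param methods Character vector of method names, or a named list of
#'   [interp_spec()] objects.
#' @param hybrid A [hybrid_config()] to evaluate the hybrid variants, or
#'   `NULL` for plain-only.
#' @param hybrid_states Which variants to run, subset of
#'   `c(FALSE, TRUE)`.
#' @param refit_nn Passed to [loocv()].
#' @return A `cv_report` tibble (method, hybrid, mae, r, ...) with the
#'   governing row in attribute `"governing"`; failed rows carry `NA`
#'   metrics and are excluded from selection.
#' @export
run_method_comparison <- function(s, parameter, methods = c("idw", "ok"),
                                  hybrid = NULL,
                                  hybrid_states = c(FALSE, TRUE),
                                  refit_nn = TRUE) {
  if (is.character(methods)) {
    methods <- setNames(lapply(methods, interp_spec), methods)
  }
  if (length(methods) < 1) abort("need at least one method")
  states <- if (is.null(hybrid)) FALSE else hybrid_states
  rows <- purrr::map_dfr(names(methods), function(nm) {
    purrr::map_dfr(states, function(h) {
      res <- tryCatch(
        loocv(methods[[nm]], s, parameter,
              hybrid = if (h) hybrid else NULL, refit_nn = refit_nn),
        error = function(e) tibble(method = methods[[nm]]$method, hybrid = h,
                                   mae = NA_real_, r = NA_real_,
                                   n_folds = NA_integer_, n_failed = NA_integer_))
      res$label <- paste0(toupper(res$method), if (h) "+NN-PSO" else "")
      res
    })
  })
  rows <- dplyr::relocate(rows, "label")
  valid <- rows[!is.na(rows$mae), ]
  if (nrow(valid) == 0) abort("every method failed cross-validation")
  out <- rows
  class(out) <- c("cv_report", class(out))
  attr(out, "governing") <- select_governing(valid)
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> leave-one-out cross-validation\n")
  print(as_tibble(x))
  g <- attr(x, "governing")
  if (!is.null(g)) {
    cat(sprintf("governing method: %s (MAE %.6g, R %.3f)\n",
                g$label %||% g$method, g$mae, g$r))
  }
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) as_tibble(x)

#' @export
glance.cv_report <- function(x, ...) {
  g <- attr(x, "governing")
  tibble(governing = g$label %||% g$method, mae = g$mae, r = g$r,
         n_methods = nrow(x))
}

#' Plot a cross-validation comparison
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot of MAE by method, split by hybrid state.
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$mae,
                                   fill = .data$hybrid)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "LOOCV MAE", fill = "NN-densified") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
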