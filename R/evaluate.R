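# Error/agreement metrics and leave-one-out cross-validation with
# MAE/Pearson-R governing-method selection.

#' Mean absolute error
#' @param pred,obs Equal-length numeric vectors.
#' @return `mean(|pred - obs|)`.
#' @export
mae <- function(pred, obs) {
  if (length(pred) != length(obs)) abort("length mismatch")
  if (length(pred) < 1) abort("need at least one pair")
  mean(abs(pred - obs))
}

#' Mean squared error
#' @inheritParams mae
#' @return `mean((obs - pred)^2)`.
#' @export
mse <- function(pred, obs) {
  if (length(pred) != length(obs)) abort("length mismatch")
  mean((obs - pred)^2)
}

#' Pearson correlation of predicted vs measured
#' @param y0 Predicted values.
#' @param ym Measured values.
#' @return Sample Pearson correlation; `NA` if either input is constant.
#' @export
pearson_r <- function(y0, ym) {
  if (length(y0) != length(ym)) abort("length mismatch")
  if (length(y0) < 3) abort("need at least 3 pairs")
  if (sd(y0) == 0 || sd(ym) == 0) return(NA_real_)
  cor(y0, ym)
}

#' Leave-one-out cross-validation of an interpolator
#'
#' Folds iterate over measured (non-pseudo) stations with a value for the
#' parameter. In each fold the held-out station is removed, the whole
#' pipeline is refit on the rest — including neural-network training and
#' pseudo-point generation when `hybrid` is supplied (set
#' `refit_nn = FALSE` for the fast mode that reuses the full-data
#' network) — and the held-out value is predicted.
#'
#' @param spec An [interp_spec()].
#' @param s Survey tibble.
#' @param parameter Parameter name.
#' @param hybrid Optional [hybrid_config()]; when given, each fold's
#'   training survey is densified with pseudo-stations first.
#' @param refit_nn Retrain the network in every fold (default TRUE).
#' @param max_fail_frac Error out when more than this fraction of folds
#'   fails (default 0.2).
#' @return One-row tibble: `method`, `hybrid`, `mae`, `r`, `n_folds`,
#'   `n_failed`. Attribute `"folds"` holds per-fold observed/predicted.
#' @export
loocv <- function(spec, s, parameter, hybrid = NULL, refit_nn = TRUE,
                  max_fail_frac = 0.2) {
  meas <- measured_stations(s)
  idx <- which(!is.na(meas[[parameter]]))
  if (length(idx) < 5) abort("need at least 5 measured stations")
  full_fit <- NULL
  if (!is.null(hybrid) && !refit_nn) {
    full_fit <- nn_fit_for(meas, hybrid)
  }
  obs <- pred <- rep(NA_real_, length(idx))
  failed <- logical(length(idx))
  for (f in seq_along(idx)) {
    i <- idx[f]
    train <- meas[-i, ]
    target <- cbind(meas$x[i], meas$y[i])
    obs[f] <- meas[[parameter]][i]
    pred[f] <- tryCatch({
      if (!is.null(hybrid)) {
        train <- augment_with_nn(train, hybrid, fit = full_fit)
      }
      predict_points(spec, train, parameter, target)
    }, error = function(e) NA_real_)
    failed[f] <- is.na(pred[f])
  }
  if (mean(failed) > max_fail_frac) {
    abort(paste0(sum(failed), "/", length(idx), " folds failed"))
  }
  ok <- !failed
  out <- tibble(
    method = spec$method,
    hybrid = !is.null(hybrid),
    mae = mae(pred[ok], obs[ok]),
    r = pearson_r(pred[ok], obs[ok]),
    n_folds = length(idx),
    n_failed = sum(failed)
  )
  attr(out, "folds") <- tibble(station = meas$station_id[idx],
                               observed = obs, predicted = pred)
  out
}

#' Select the governing method
#'
#' The row with the smallest MAE wins; MAE ties (within 1e-12) are broken
#' by the larger Pearson R.
#'
#' @param rows A cross-validation report (tibble with `mae` and `r`).
#' @return The winning row.
#' @export
select_governing <- function(rows) {
  if (nrow(rows) < 1) abort("empty cross-validation report")
  best_mae <- min(rows$mae)
  cand <- rows[rows$mae <= best_mae + 1e-12, ]
  cand[which.max(cand$r), ]
}
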