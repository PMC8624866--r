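# Ordinary, universal and (simplified) empirical Bayesian kriging.

# assemble and solve the kriging system for a set of targets.
# drift: NULL for OK (constant only) or a function(x, y) -> design matrix
kriging_solve <- function(pts, vm, tm, drift_fun = NULL,
                          filter_nugget = FALSE) {
  n <- length(pts$z)
  D <- pair_dist(pts$x, pts$y, pts$x, pts$y)
  if (n > 1 && min(D[upper.tri(D)]) < 1e-9) {
    idx <- which(D < 1e-9 & upper.tri(D), arr.ind = TRUE)[1, ]
    abort(paste0("coincident stations make the kriging matrix singular ",
                 "(stations ", idx[1], " and ", idx[2], "); average them first"))
  }
  G <- vgm_eval(vm, D)
  Fm <- if (is.null(drift_fun)) matrix(1, n, 1) else drift_fun(pts$x, pts$y)
  m <- ncol(Fm)
  A <- rbind(cbind(G, Fm), cbind(t(Fm), matrix(0, m, m)))
  D0 <- pair_dist(pts$x, pts$y, tm[, 1], tm[, 2])
  g0 <- vgm_eval(vm, D0)                                         # n x nt
  # nugget-filtered smoothing: a zero-distance target sees the nugget
  # (limit from above) instead of gamma(0) = 0, so kriging smooths
  # through the measurement-error component rather than honouring it
  if (filter_nugget) g0[D0 < 1e-9] <- vm$nugget
  F0 <- if (is.null(drift_fun)) matrix(1, 1, nrow(tm))
        else t(drift_fun(tm[, 1], tm[, 2]))
  B <- rbind(g0, F0)
  sol <- tryCatch(solve(A, B), error = function(e) {
    abort("singular kriging matrix; check station geometry and drift")
  })
  W <- unname(sol[1:n, , drop = FALSE])   # weights, n x nt
  MU <- unname(sol[(n + 1):(n + m), , drop = FALSE])
  pred <- unname(drop(crossprod(W, pts$z)))
  vari <- unname(colSums(W * g0) + colSums(MU * F0))
  vari <- pmax(vari, 0)
  list(pred = pred, var = vari, weights = W)
}

exactify <- function(pred, pts, tm) {
  # at-station convention: return the measured value
  D0 <- pair_dist(tm[, 1], tm[, 2], pts$x, pts$y)
  for (i in seq_len(nrow(tm))) {
    hit <- D0[i, ] < 1e-9
    if (any(hit)) pred[i] <- mean(pts$z[hit])
  }
  pred
}

#' Ordinary kriging prediction
#'
#' Solves, per target, the ordinary kriging system with unit-sum weight
#' constraint; returns the BLUP and the kriging variance. Predictions at
#' station locations return the measured value (set `exact = FALSE` for
#' nugget-filtered smoothing instead).
#'
#' @param s Survey tibble with projected coordinates.
#' @param parameter Parameter name.
#' @param vm A `variogram_model` (fit one with [fit_variogram()]).
#' @param targets Prediction locations.
#' @param exact Return measured values at stations (default TRUE).
#' @param dedupe_tol Coincident stations closer than this (m) are averaged.
#' @return Tibble with `pred` and `var`; attribute `"weights"` holds the
#'   stations-by-targets weight matrix.
#' @export
ok_predict <- function(s, parameter, vm, targets, exact = TRUE,
                       dedupe_tol = 10) {
  pts <- dedupe_points(survey_points(s, parameter), tol = dedupe_tol)
  tm <- as_target_matrix(targets)
  out <- kriging_solve(pts, vm, tm, filter_nugget = !exact)
  pred <- if (exact) exactify(out$pred, pts, tm) else out$pred
  res <- tibble(pred = pred, var = out$var)
  attr(res, "weights") <- out$weights
  res
}

#' Universal kriging prediction
#'
#' Ordinary kriging augmented with a deterministic drift in the
#' unbiasedness constraints: `drift = "linear"` uses `{1, x, y}`;
#' `drift = "constant"` reduces exactly to ordinary kriging.
#'
#' @inheritParams ok_predict
#' @param drift `"linear"` (default) or `"constant"`.
#' @return Tibble with `pred` and `var`.
#' @export
uk_predict <- function(s, parameter, vm, targets,
                       drift = c("linear", "constant"), exact = TRUE,
                       dedupe_tol = 10) {
  drift <- match.arg(drift)
  pts <- dedupe_points(survey_points(s, parameter), tol = dedupe_tol)
  tm <- as_target_matrix(targets)
  drift_fun <- NULL
  if (drift == "linear") {
    if (length(pts$z) < 4) abort("need >= 4 stations for linear drift")
    cx <- mean(pts$x); cy <- mean(pts$y)
    sc <- max(sd(pts$x), sd(pts$y), 1)
    drift_fun <- function(x, y) cbind(1, (x - cx) / sc, (y - cy) / sc)
    dm <- drift_fun(pts$x, pts$y)
    if (qr(dm)$rank < 3) abort("collinear stations: linear drift unidentifiable")
  }
  out <- kriging_solve(pts, vm, tm, drift_fun, filter_nugget = !exact)
  pred <- if (exact) exactify(out$pred, pts, tm) else out$pred
  res <- tibble(pred = pred, var = out$var)
  attr(res, "weights") <- out$weights
  res
}

#' Simplified empirical Bayesian kriging
#'
#' Propagates variogram-estimation uncertainty: a base variogram is fit to
#' the data, then repeatedly an unconditional Gaussian realization is
#' drawn at the station locations from the base model and a variogram is
#' refit to it, giving an equal-weight ensemble of `K` models (member 1 is
#' the base fit, so `K = 1` reduces to ordinary kriging). The prediction
#' is the ensemble mean of the member OK predictions; the variance is the
#' mean member variance plus the between-member spread. For surveys larger
#' than `subset_size`, stations are split into overlapping spatial subsets
#' and each target uses its nearest subset's ensemble.
#'
#' @inheritParams ok_predict
#' @param K Ensemble size (default 100).
#' @param subset_size Maximum stations per local ensemble (default 50).
#' @param seed Integer seed; the ensemble is deterministic given it.
#' @param families Candidate families for the (re)fits.
#' @param n_lags Lag bins for the empirical variograms.
#' @return Tibble with `pred` and `var`; attributes `"ensemble"` (list of
#'   `variogram_model`) and `"base_model"`.
#' @export
ebk_predict <- function(s, parameter, targets, K = 100, subset_size = 50,
                        seed = 1, families = c("spherical", "exponential",
                                               "gaussian"),
                        n_lags = 12, exact = TRUE, dedupe_tol = 10) {
  if (K < 1) abort("K must be >= 1")
  pts <- dedupe_points(survey_points(s, parameter), tol = dedupe_tol)
  n <- length(pts$z)
  if (n < 10) abort("need at least 10 stations")
  tm <- as_target_matrix(targets)
  withr::local_seed(seed)

  subsets <- if (n <= subset_size) list(seq_len(n)) else {
    km <- stats::kmeans(cbind(pts$x, pts$y), ceiling(n / subset_size),
                        nstart = 3)
    lapply(seq_len(max(km$cluster)), function(g) {
      core <- which(km$cluster == g)
      # overlap: grow each subset with its nearest outside stations
      need <- min(subset_size, n) - length(core)
      if (need > 0) {
        cx <- mean(pts$x[core]); cy <- mean(pts$y[core])
        d <- sqrt((pts$x - cx)^2 + (pts$y - cy)^2)
        d[core] <- Inf
        core <- c(core, order(d)[seq_len(need)])
      }
      sort(core)
    })
  }

  sub_fit <- lapply(subsets, function(idx) {
    sp <- list(x = pts$x[idx], y = pts$y[idx], z = pts$z[idx],
               w = pts$w[idx])
    ev <- empirical_variogram_xyz(sp$x, sp$y, sp$z, n_lags = n_lags)
    base <- fit_variogram(ev, families)
    members <- list(base)
    dropped <- 0
    if (K > 1) {
      for (k in 2:K) {
        zsim <- grf_draw(sp$x, sp$y, base) + mean(sp$z)
        mem <- tryCatch({
          evk <- empirical_variogram_xyz(sp$x, sp$y, zsim, n_lags = n_lags)
          fit_variogram(evk, families)
        }, error = function(e) NULL)
        if (is.null(mem) || mem$psill + mem$nugget <= 0) dropped <- dropped + 1
        else members[[length(members) + 1]] <- mem
      }
      if (dropped > 0) {
        warn(paste0(dropped, " ensemble member(s) failed to fit and were dropped"))
        if (length(members) < K / 2) abort("fewer than K/2 ensemble members survived")
      }
    }
    list(idx = idx, pts = sp, members = members,
         cx = mean(sp$x), cy = mean(sp$y))
  })

  # each target uses the nearest subset's ensemble
  assign <- if (length(sub_fit) == 1) rep(1L, nrow(tm)) else {
    cen <- do.call(rbind, lapply(sub_fit, function(f) c(f$cx, f$cy)))
    apply(pair_dist(tm[, 1], tm[, 2], cen[, 1], cen[, 2]), 1, which.min)
  }

  pred <- numeric(nrow(tm)); vari <- numeric(nrow(tm))
  for (gi in unique(assign)) {
    ti <- which(assign == gi)
    f <- sub_fit[[gi]]
    preds <- vars <- matrix(NA_real_, length(f$members), length(ti))
    for (k in seq_along(f$members)) {
      out <- kriging_solve(f$pts, f$members[[k]], tm[ti, , drop = FALSE])
      preds[k, ] <- out$pred; vars[k, ] <- out$var
    }
    pred[ti] <- colMeans(preds)
    between <- if (nrow(preds) > 1) {
      colMeans(sweep(preds, 2, colMeans(preds))^2)
    } else 0
    vari[ti] <- colMeans(vars) + between
  }
  if (exact) pred <- exactify(pred, pts, tm)
  res <- tibble(pred = pred, var = vari)
  attr(res, "ensemble") <- purrr::flatten(lapply(sub_fit, function(f) f$members))
  attr(res, "base_model") <- sub_fit[[1]]$members[[1]]
  res
}

# unconditional zero-mean Gaussian draw at given points under a variogram
grf_draw <- function(x, y, vm, jitter = 1e-10) {
  D <- pair_dist(x, y, x, y)
  C <- vgm_cov(vm, D)
  diag(C) <- diag(C) + jitter * max(diag(C), 1)
  L <- tryCatch(chol(C), error = function(e) {
    abort("covariance not positive definite even after jitter")
  })
  drop(crossprod(L, rnorm(length(x))))
}
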