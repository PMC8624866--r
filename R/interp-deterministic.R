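# Deterministic interpolators: inverse distance weighting (IDW), global
# polynomial (GPI), local polynomial (LPI), radial basis functions (RBF)
# and kernel smoothing (KS = ridge-regularised first-order LPI, optionally
# with barrier-avoiding distances).

as_target_matrix <- function(targets) {
  if (is.matrix(targets)) {
    m <- targets
  } else if (is.data.frame(targets)) {
    m <- cbind(targets$x, targets$y)
  } else if (is.numeric(targets) && length(targets) == 2) {
    m <- matrix(targets, 1)
  } else {
    abort("targets must be a matrix, a data frame with x/y, or an xy pair")
  }
  storage.mode(m) <- "double"
  m
}

# non-missing observations of one parameter, with planar coordinates
survey_points <- function(s, parameter, weights = FALSE) {
  if (!parameter %in% names(s)) {
    abort(paste0("parameter not present in survey: ", parameter))
  }
  if (!"x" %in% names(s) || anyNA(s$x)) {
    abort("survey has no projected coordinates; call project_utm() first")
  }
  keep <- !is.na(s[[parameter]])
  if (!any(keep)) abort(paste0("no non-missing values for ", parameter))
  list(x = s$x[keep], y = s$y[keep], z = s[[parameter]][keep],
       w = if ("obs_weight" %in% names(s)) s$obs_weight[keep]
           else rep(1, sum(keep)))
}

# average coincident points (within tol meters); exact interpolators need
# distinct support points
dedupe_points <- function(pts, tol = 10) {
  n <- length(pts$x)
  if (n < 2 || tol <= 0) return(pts)
  group <- seq_len(n)
  for (i in 2:n) for (j in 1:(i - 1)) {
    if (sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2) <= tol) {
      group[group == group[i]] <- group[j]
      break
    }
  }
  ug <- unique(group)
  list(
    x = vapply(ug, function(g) mean(pts$x[group == g]), 0),
    y = vapply(ug, function(g) mean(pts$y[group == g]), 0),
    z = vapply(ug, function(g) mean(pts$z[group == g]), 0),
    w = vapply(ug, function(g) mean(pts$w[group == g]), 0)
  )
}

pair_dist <- function(x1, y1, x2, y2) {
  # cross-distance matrix, rows = (x1,y1), cols = (x2,y2)
  sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
}

#' Inverse distance weighted prediction
#'
#' Weighted average of the `k` nearest observations with weights
#' `d^(-p)`. Exact at sample locations: a target within 1e-9 m of a
#' station returns that station's value (coincident duplicates averaged).
#'
#' @param s Survey tibble with projected coordinates.
#' @param parameter Parameter to interpolate.
#' @param targets Prediction locations (matrix or data frame with x/y).
#' @param p Distance-decay power (> 0), default 2.
#' @param k Number of nearest neighbours (default 15, capped at n).
#' @return Numeric vector of predictions.
#' @export
idw_predict <- function(s, parameter, targets, p = 2, k = 15) {
  if (p <= 0) abort("power p must be > 0")
  pts <- survey_points(s, parameter)
  tm <- as_target_matrix(targets)
  k <- min(k, length(pts$z))
  D <- pair_dist(tm[, 1], tm[, 2], pts$x, pts$y)
  vapply(seq_len(nrow(tm)), function(i) {
    d <- D[i, ]
    hit <- d < 1e-9
    if (any(hit)) return(mean(pts$z[hit]))
    nb <- order(d)[seq_len(k)]
    w <- d[nb]^(-p)
    sum(w * pts$z[nb]) / sum(w)
  }, 0)
}

poly_design <- function(u, v, degree) {
  cols <- list(rep(1, length(u)))
  nm <- "1"
  for (d in 1:degree) for (i in 0:d) {
    cols <- c(cols, list(u^(d - i) * v^i))
    nm <- c(nm, paste0("u", d - i, "v", i))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Global polynomial trend-surface prediction
#'
#' Ordinary least squares fit of a full bivariate polynomial of the given
#' degree on standardized coordinates, evaluated at the targets.
#'
#' @inheritParams idw_predict
#' @param degree Polynomial degree, 1 to 3.
#' @return Numeric vector of predictions.
#' @export
gpi_fit_predict <- function(s, parameter, targets, degree = 1) {
  if (!degree %in% 1:3) abort("degree must be 1, 2 or 3")
  pts <- survey_points(s, parameter)
  n_terms <- (degree + 1) * (degree + 2) / 2
  if (length(pts$z) < n_terms) {
    abort(paste0("need at least ", n_terms, " stations for degree ", degree))
  }
  cx <- mean(pts$x); cy <- mean(pts$y)
  sc <- max(sd(pts$x), sd(pts$y), 1)
  X <- poly_design((pts$x - cx) / sc, (pts$y - cy) / sc, degree)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort(paste0("rank-deficient design (degenerate geometry); ",
                 "try a lower degree"))
  }
  beta <- qr.coef(qrX, pts$z)
  tm <- as_target_matrix(targets)
  Xt <- poly_design((tm[, 1] - cx) / sc, (tm[, 2] - cy) / sc, degree)
  drop(Xt %*% beta)
}

#' Local polynomial prediction
#'
#' At each target, weighted least squares of a polynomial of the given
#' degree with Gaussian kernel weights `exp(-(d/bandwidth)^2)`. An
#' optional ridge penalty `delta` on the non-intercept terms of the
#' normal matrix turns this into the kernel-smoothing interpolator; large
#' `delta` shrinks the prediction toward the locally weighted mean.
#'
#' @inheritParams idw_predict
#' @param degree Local polynomial degree (default 1).
#' @param bandwidth Gaussian kernel bandwidth in meters (default: half the
#'   survey bounding-box diagonal).
#' @param delta Ridge factor >= 0 (0 = plain local WLS).
#' @param distances Optional precomputed targets-by-stations distance
#'   matrix (used by the barrier variant).
#' @param min_weight Neighbours with kernel weight below this are ignored.
#' @return Numeric vector of predictions; `NA` (with a warning) where too
#'   few in-range neighbours exist.
#' @export
lpi_predict <- function(s, parameter, targets, degree = 1, bandwidth = NULL,
                        delta = 0, distances = NULL, min_weight = 1e-12) {
  if (delta < 0) abort("ridge factor delta must be >= 0")
  pts <- survey_points(s, parameter)
  tm <- as_target_matrix(targets)
  bandwidth <- bandwidth %||% default_bandwidth(pts)
  if (bandwidth <= 0) abort("bandwidth must be > 0")
  n_terms <- (degree + 1) * (degree + 2) / 2
  D <- distances %||% pair_dist(tm[, 1], tm[, 2], pts$x, pts$y)
  out <- rep(NA_real_, nrow(tm))
  any_dropped <- FALSE
  for (i in seq_len(nrow(tm))) {
    w <- exp(-(D[i, ] / bandwidth)^2) * pts$w
    use <- w > min_weight
    if (sum(use) < n_terms) { any_dropped <- TRUE; next }
    # local coordinates normalised by the neighbourhood spread (not the
    # bandwidth) so wide kernels keep a well-conditioned design
    sc <- max(sd(pts$x[use]), sd(pts$y[use]), 1e-12)
    u <- (pts$x[use] - tm[i, 1]) / sc
    v <- (pts$y[use] - tm[i, 2]) / sc
    X <- poly_design(u, v, degree)
    A <- crossprod(X * sqrt(w[use]))
    b <- crossprod(X, w[use] * pts$z[use])
    if (delta > 0) {
      pen <- diag(ncol(A)) * delta
      pen[1, 1] <- 0  # never shrink the intercept
      A <- A + pen
    }
    beta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(beta)) { any_dropped <- TRUE; next }
    out[i] <- beta[1]
  }
  if (any_dropped) warn("some targets had too few in-range neighbours; nodata returned")
  out
}

default_bandwidth <- function(pts) {
  sqrt(diff(range(pts$x))^2 + diff(range(pts$y))^2) / 2
}

#' Kernel-smoothing prediction (with optional barriers)
#'
#' First-order local polynomial with a ridge penalty (`delta > 0`), the
#' regularisation used to stabilise local regression coefficients. When
#' `barriers` are supplied, distances are shortest straight-line paths
#' that do not cross any barrier segment (see [barrier_distance()]).
#'
#' @inheritParams lpi_predict
#' @param barriers Optional barrier polylines: a list of two-column
#'   matrices of vertices, each row a vertex of an open polyline.
#' @return Numeric vector of predictions.
#' @export
ks_predict <- function(s, parameter, targets, bandwidth = NULL, delta = 1e-3,
                       barriers = NULL) {
  pts <- survey_points(s, parameter)
  tm <- as_target_matrix(targets)
  D <- NULL
  if (!is.null(barriers)) {
    D <- barrier_distance(tm, cbind(pts$x, pts$y), barriers)
  }
  lpi_predict(s, parameter, targets, degree = 1, bandwidth = bandwidth,
              delta = delta, distances = D)
}

rbf_kernel <- function(r, kernel, eps) {
  switch(kernel,
    thin_plate_spline = ifelse(r == 0, 0, r^2 * log(r)),
    multiquadric = sqrt(1 + (eps * r)^2),
    inverse_multiquadric = 1 / sqrt(1 + (eps * r)^2),
    gaussian = exp(-(eps * r)^2),
    abort(paste0("unknown RBF kernel: ", kernel)))
}

#' Radial basis function interpolation
#'
#' Exact interpolation by a kernel expansion with polynomial drift: an
#' affine term for the thin-plate spline (`r^2 log r`, the
#' minimum-curvature choice and the default) and the multiquadric, a
#' constant term for the Gaussian and inverse multiquadric. Coincident
#' stations are averaged before fitting.
#'
#' @inheritParams idw_predict
#' @param kernel One of `"thin_plate_spline"`, `"multiquadric"`,
#'   `"inverse_multiquadric"`, `"gaussian"`.
#' @param eps Shape parameter (> 0) for the scaled kernels; ignored by the
#'   thin-plate spline. Default `1/median nonzero pair distance`.
#' @param dedupe_tol Stations closer than this (meters) are averaged.
#' @return Numeric vector of predictions.
#' @export
rbf_fit_predict <- function(s, parameter, targets,
                            kernel = c("thin_plate_spline", "multiquadric",
                                       "inverse_multiquadric", "gaussian"),
                            eps = NULL, dedupe_tol = 10) {
  kernel <- match.arg(kernel)
  pts <- dedupe_points(survey_points(s, parameter), tol = dedupe_tol)
  n <- length(pts$z)
  if (n < 3) abort("need at least 3 distinct stations")
  D <- pair_dist(pts$x, pts$y, pts$x, pts$y)
  r0 <- max(median(D[upper.tri(D)]), .Machine$double.eps)
  if (is.null(eps)) eps <- 1 / r0
  if (eps <= 0) abort("shape parameter eps must be > 0")
  cx <- mean(pts$x); cy <- mean(pts$y)
  sc <- max(sd(pts$x), sd(pts$y), 1)
  # thin-plate kernel evaluated on distances scaled by the median pair
  # distance: conditions the system without changing exactness
  K <- rbf_kernel(D / r0, kernel, eps * r0)
  P <- if (kernel %in% c("thin_plate_spline", "multiquadric")) {
    cbind(1, (pts$x - cx) / sc, (pts$y - cy) / sc)
  } else {
    matrix(1, n, 1)
  }
  m <- ncol(P)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, m, m)))
  rhs <- c(pts$z, rep(0, m))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    abort("singular RBF system; de-duplicate coincident stations")
  })
  lambda <- sol[1:n]; beta <- sol[(n + 1):(n + m)]
  tm <- as_target_matrix(targets)
  Kt <- rbf_kernel(pair_dist(tm[, 1], tm[, 2], pts$x, pts$y) / r0,
                   kernel, eps * r0)
  Pt <- if (m == 3) cbind(1, (tm[, 1] - cx) / sc, (tm[, 2] - cy) / sc)
        else matrix(1, nrow(tm), 1)
  drop(Kt %*% lambda + Pt %*% beta)
}
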