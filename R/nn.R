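# Single-hidden-layer tansig feedforward network with min-max scaling,
# 70/15/15 partitioning and Levenberg-Marquardt training.

#' Split indices into training/validation/test sets
#'
#' 70/15/15 random partition: validation and test each get
#' `floor(0.15 n)` indices, the remainder trains. Deterministic per seed.
#'
#' @param n Number of observations (>= 7).
#' @param seed Integer seed.
#' @return List with integer vectors `train`, `validation`, `test`.
#' @export
partition_data <- function(n, seed = 1) {
  if (n < 7) abort("need at least 7 observations to partition 70/15/15")
  withr::local_seed(seed)
  n_val <- floor(0.15 * n)
  n_test <- floor(0.15 * n)
  idx <- sample.int(n)
  list(validation = sort(idx[seq_len(n_val)]),
       test = sort(idx[n_val + seq_len(n_test)]),
       train = sort(idx[(n_val + n_test + 1):n]))
}

minmax_params <- function(M, lo = -1, hi = 1) {
  mn <- apply(M, 2, min); mx <- apply(M, 2, max)
  span <- mx - mn
  span[span == 0] <- 1
  list(min = mn, span = span, lo = lo, hi = hi)
}

minmax_scale <- function(M, p) {
  sweep(sweep(M, 2, p$min), 2, p$span, "/") * (p$hi - p$lo) + p$lo
}

minmax_unscale <- function(M, p) {
  sweep(sweep((M - p$lo) / (p$hi - p$lo), 2, p$span, "*"), 2, p$min, "+")
}

#' Initialise a tansig network
#'
#' Architecture: `n_in` inputs, one hidden layer of `n_hidden` tansig
#' units, one tansig output. Inputs are min-max scaled to `[-1, 1]`;
#' targets to `[-0.9, 0.9]` so extreme training targets stay inside the
#' open range of the output activation.
#'
#' @param X Input matrix (rows = observations).
#' @param y Target vector.
#' @param n_hidden Hidden units (studies of this kind use 20-30; smaller
#'   nets suffice at desk scale).
#' @param seed Seed for the uniform `[-0.5, 0.5]` weight initialisation.
#' @return An `mlp_model` (weights `W1`, `b1`, `W2`, `b2` + scalers).
#' @export
mlp_init <- function(X, y, n_hidden = 10, seed = 1) {
  X <- as.matrix(X)
  withr::local_seed(seed)
  n_in <- ncol(X)
  sx <- minmax_params(X, -1, 1)
  sy <- minmax_params(matrix(y, ncol = 1), -0.9, 0.9)
  structure(list(
    n_in = n_in, n_hidden = n_hidden,
    W1 = matrix(runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
    b1 = runif(n_hidden, -0.5, 0.5),
    W2 = matrix(runif(n_hidden, -0.5, 0.5), 1, n_hidden),
    b2 = runif(1, -0.5, 0.5),
    scale_x = sx, scale_y = sy
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%d-1 tansig network (%d weights)\n",
              x$n_in, x$n_hidden, n_params(x)))
  invisible(x)
}

n_params <- function(m) m$n_hidden * m$n_in + m$n_hidden + m$n_hidden + 1

flatten_params <- function(m) c(m$W1, m$b1, m$W2, m$b2)

unflatten_params <- function(m, theta) {
  nh <- m$n_hidden; ni <- m$n_in
  m$W1 <- matrix(theta[seq_len(nh * ni)], nh, ni)
  off <- nh * ni
  m$b1 <- theta[off + seq_len(nh)]; off <- off + nh
  m$W2 <- matrix(theta[off + seq_len(nh)], 1, nh); off <- off + nh
  m$b2 <- theta[off + 1]
  m
}

# forward pass in scaled space; X already scaled
forward_scaled <- function(m, Xs) {
  H <- tanh(sweep(Xs %*% t(m$W1), 2, m$b1, "+"))   # n x nh
  o <- tanh(drop(H %*% t(m$W2)) + m$b2)
  list(H = H, o = o)
}

#' Network predictions in original units
#'
#' `unscale(tanh(W2 tanh(W1 scale(x) + b1) + b2))`.
#'
#' @param m An `mlp_model`.
#' @param X Input matrix in original units (`ncol = n_in`).
#' @return Numeric vector of predictions.
#' @export
mlp_forward <- function(m, X) {
  X <- as.matrix(X)
  if (ncol(X) != m$n_in) abort("input column count does not match n_in")
  Xs <- minmax_scale(X, m$scale_x)
  o <- forward_scaled(m, Xs)$o
  drop(minmax_unscale(matrix(o, ncol = 1), m$scale_y))
}

# Jacobian of scaled outputs wrt all parameters, via backpropagation
mlp_jacobian <- function(m, Xs) {
  n <- nrow(Xs); nh <- m$n_hidden; ni <- m$n_in
  fw <- forward_scaled(m, Xs)
  do <- 1 - fw$o^2                       # n
  dH <- 1 - fw$H^2                       # n x nh
  gW2 <- do * fw$H                       # n x nh
  gb2 <- do                              # n
  gb1 <- do * dH * matrix(m$W2, n, nh, byrow = TRUE)   # n x nh
  gW1 <- matrix(0, n, nh * ni)
  for (k in seq_len(ni)) {
    gW1[, (k - 1) * nh + seq_len(nh)] <- gb1 * Xs[, k]
  }
  cbind(gW1, gb1, gW2, gb2)
}

mse_scaled <- function(m, Xs, ys) mean((ys - forward_scaled(m, Xs)$o)^2)

#' Levenberg-Marquardt training
#'
#' Minimises the training-partition sum of squared errors in scaled
#' units. The damping factor is multiplied by 10 on a rejected step and
#' divided by 10 on an accepted one; training stops at `max_iter`,
#' gradient norm below `grad_tol`, or after `max_val_fail` consecutive
#' increases of the validation MSE (early stopping). The returned model
#' carries the weights with the best validation MSE seen.
#'
#' @param m An `mlp_model` from [mlp_init()].
#' @param X,y Data in original units.
#' @param part Partition from [partition_data()].
#' @param lambda0 Initial damping (default 1e-3).
#' @param max_iter Iteration cap (default 1000).
#' @param max_val_fail Early-stopping patience (default 6).
#' @param grad_tol Gradient-norm stopping threshold (default 1e-7).
#' @return List: `model` (best-validation weights) and `report`, a
#'   one-row tibble with `mse` (training, scaled units), `r_validation`,
#'   `r_testing`, `iterations`, `elapsed_s`.
#' @export
train_lm <- function(m, X, y, part, lambda0 = 1e-3, max_iter = 1000,
                     max_val_fail = 6, grad_tol = 1e-7) {
  t0 <- proc.time()[3]
  X <- as.matrix(X)
  if (nrow(X) != length(y)) abort("X rows and y length differ")
  if (max(c(part$train, part$validation, part$test)) > length(y)) {
    abort("partition inconsistent with data length")
  }
  Xs <- minmax_scale(X, m$scale_x)
  ys <- drop(minmax_scale(matrix(y, ncol = 1), m$scale_y))
  Xtr <- Xs[part$train, , drop = FALSE]; ytr <- ys[part$train]
  Xva <- Xs[part$validation, , drop = FALSE]; yva <- ys[part$validation]
  lambda <- lambda0
  best <- m
  best_val <- if (length(yva) > 0) mse_scaled(m, Xva, yva) else Inf
  val_fail <- 0
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    fw <- forward_scaled(m, Xtr)
    r <- ytr - fw$o
    if (!all(is.finite(r))) abort(paste0("non-finite loss at iteration ", iter))
    J <- mlp_jacobian(m, Xtr)
    g <- crossprod(J, r)
    if (sqrt(sum(g^2)) < grad_tol) break
    JtJ <- crossprod(J)
    sse <- sum(r^2)
    repeat {
      step <- tryCatch(
        solve(JtJ + lambda * diag(ncol(J)), g),
        error = function(e) NULL)
      cand <- if (is.null(step)) NULL else
        unflatten_params(m, flatten_params(m) + drop(step))
      new_sse <- if (is.null(cand)) Inf else {
        rc <- ytr - forward_scaled(cand, Xtr)$o
        sum(rc^2)
      }
      if (is.finite(new_sse) && new_sse < sse) {
        m <- cand
        lambda <- max(lambda / 10, 1e-12)
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e10) break
    }
    if (lambda > 1e10) break
    if (length(yva) > 0) {
      val <- mse_scaled(m, Xva, yva)
      if (val < best_val) {
        best_val <- val; best <- m; val_fail <- 0
      } else {
        val_fail <- val_fail + 1
        if (val_fail >= max_val_fail) break
      }
    } else {
      best <- m
    }
  }
  if (length(yva) == 0) best <- m
  report <- train_report(best, X, y, part, iterations = iter,
                         elapsed_s = proc.time()[3] - t0)
  structure(list(model = best, report = report), class = "mlp_fit")
}

train_report <- function(m, X, y, part, iterations, elapsed_s) {
  Xs <- minmax_scale(as.matrix(X), m$scale_x)
  ys <- drop(minmax_scale(matrix(y, ncol = 1), m$scale_y))
  pred <- mlp_forward(m, X)
  rr <- function(idx) {
    if (length(idx) < 3 || sd(y[idx]) == 0 || sd(pred[idx]) == 0) NA_real_
    else cor(pred[idx], y[idx])
  }
  tibble(
    mse = mean((ys[part$train] - forward_scaled(m, Xs[part$train, , drop = FALSE])$o)^2),
    r_validation = rr(part$validation),
    r_testing = rr(part$test),
    iterations = iterations,
    elapsed_s = unname(elapsed_s)
  )
}

#' @export
glance.mlp_fit <- function(x, ...) x$report

#' @export
tidy.mlp_fit <- function(x, ...) {
  m <- x$model
  tibble(term = c(paste0("W1[", seq_along(m$W1), "]"),
                  paste0("b1[", seq_along(m$b1), "]"),
                  paste0("W2[", seq_along(m$W2), "]"), "b2"),
         estimate = flatten_params(m))
}
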