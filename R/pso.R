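# Particle swarm optimisation and the PSO-initialised network trainer.

#' PSO configuration
#'
#' Canonical constriction-equivalent coefficients (Clerc-Kennedy:
#' inertia 0.729, cognitive = social = 1.49445). Positions are clamped to
#' `[-bound, bound]` and velocities to half that box.
#'
#' @param n_particles Swarm size (>= 1; single-particle swarms degenerate
#'   to a personal-best random walk and are supported).
#' @param n_iterations Iteration count.
#' @param inertia,cognitive,social Update coefficients.
#' @param bound Half-width of the search box (default 2, suited to
#'   tanh-scaled network weights).
#' @param velocity_clamp Maximum |velocity| (default `0.5 * bound`).
#' @param seed Integer seed.
#' @return A `pso_config` list.
#' @export
pso_config <- function(n_particles = 10, n_iterations = 200,
                       inertia = 0.729, cognitive = 1.49445,
                       social = 1.49445, bound = 2,
                       velocity_clamp = NULL, seed = 1) {
  if (n_particles < 1) abort("n_particles must be >= 1")
  if (n_iterations < 0) abort("n_iterations must be >= 0")
  if (!is.finite(bound) || bound <= 0) abort("bound must be finite and > 0")
  structure(list(n_particles = n_particles, n_iterations = n_iterations,
                 inertia = inertia, cognitive = cognitive, social = social,
                 bound = bound,
                 velocity_clamp = velocity_clamp %||% (0.5 * bound),
                 seed = seed),
            class = "pso_config")
}

#' Minimise an objective by particle swarm
#'
#' Canonical update `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`,
#' position clamped to the box. The global-best value is nonincreasing
#' over iterations and the whole run is deterministic given the seed.
#'
#' @param f Objective: function of a numeric vector, finite on the box.
#' @param dim Dimension of the search space.
#' @param cfg A [pso_config()].
#' @return List: `par` (best position), `value`, and `trace` (tibble of
#'   iteration vs gbest value).
#' @export
pso_minimize <- function(f, dim, cfg = pso_config()) {
  withr::local_seed(cfg$seed)
  np <- cfg$n_particles; B <- cfg$bound; vc <- cfg$velocity_clamp
  X <- matrix(runif(np * dim, -B, B), np, dim)
  V <- matrix(runif(np * dim, -vc, vc), np, dim)
  fx <- apply(X, 1, f)
  for (tries in seq_len(100)) {
    bad <- !is.finite(fx)
    if (!any(bad)) break
    X[bad, ] <- matrix(runif(sum(bad) * dim, -B, B), sum(bad), dim)
    fx[bad] <- apply(X[bad, , drop = FALSE], 1, f)
  }
  if (any(!is.finite(fx))) abort("objective non-finite after 100 resamples")
  P <- X; fp <- fx
  g <- which.min(fp)
  gbest <- P[g, ]; fg <- fp[g]
  trace <- numeric(cfg$n_iterations)
  if (cfg$n_iterations > 0) for (it in seq_len(cfg$n_iterations)) {
    r1 <- matrix(runif(np * dim), np, dim)
    r2 <- matrix(runif(np * dim), np, dim)
    V <- cfg$inertia * V +
      cfg$cognitive * r1 * (P - X) +
      cfg$social * r2 * (matrix(gbest, np, dim, byrow = TRUE) - X)
    V <- pmin(pmax(V, -vc), vc)
    X <- pmin(pmax(X + V, -B), B)
    fx <- apply(X, 1, f)
    improved <- is.finite(fx) & fx < fp
    P[improved, ] <- X[improved, ]
    fp[improved] <- fx[improved]
    g <- which.min(fp)
    if (fp[g] < fg) { fg <- fp[g]; gbest <- P[g, ] }
    trace[it] <- fg
  }
  list(par = gbest, value = fg,
       trace = tibble(iteration = seq_len(cfg$n_iterations), gbest = trace))
}

#' PSO-initialised network training
#'
#' The swarm searches the flattened weight space with training-partition
#' MSE (scaled units) as fitness; Levenberg-Marquardt then refines from
#' the global best (the swarm "informs" the initialisation). With
#' `cfg$n_iterations = 0` this is LM from a random initialisation. The
#' refined model never has worse training MSE than the swarm's best.
#'
#' @param X,y Data in original units.
#' @param part Partition from [partition_data()].
#' @param n_hidden Hidden units.
#' @param cfg A [pso_config()]; its seed also seeds the initial weights.
#' @param ... Passed to [train_lm()] (e.g. `max_iter`).
#' @return An `mlp_fit`: list with `model`, `report`, `pso_value`,
#'   `trace`.
#' @export
train_nn_pso <- function(X, y, part, n_hidden = 10, cfg = pso_config(), ...) {
  X <- as.matrix(X)
  m0 <- mlp_init(X, y, n_hidden = n_hidden, seed = cfg$seed)
  Xs <- minmax_scale(X, m0$scale_x)
  ys <- drop(minmax_scale(matrix(y, ncol = 1), m0$scale_y))
  Xtr <- Xs[part$train, , drop = FALSE]; ytr <- ys[part$train]
  dim <- n_params(m0)
  fitness <- function(theta) {
    mm <- unflatten_params(m0, theta)
    mean((ytr - forward_scaled(mm, Xtr)$o)^2)
  }
  if (cfg$n_iterations > 0) {
    sw <- pso_minimize(fitness, dim, cfg)
    m0 <- unflatten_params(m0, sw$par)
    pso_value <- sw$value
    trace <- sw$trace
  } else {
    pso_value <- fitness(flatten_params(m0))
    trace <- tibble(iteration = integer(), gbest = numeric())
  }
  fit <- train_lm(m0, X, y, part, ...)
  # LM refinement must not end worse than the swarm's best training MSE
  if (fit$report$mse > pso_value + 1e-15) {
    fit$model <- m0
    fit$report <- train_report(m0, X, y, part,
                               iterations = fit$report$iterations,
                               elapsed_s = fit$report$elapsed_s)
  }
  fit$pso_value <- pso_value
  fit$trace <- trace
  fit
}
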