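test_that("IDW is exact at stations and matches hand arithmetic", {
  s <- xy_survey(c(0, 1000), c(0, 0), c(0, 1))
  # weights 250^-2 and 750^-2 -> prediction 0.1
  expect_equal(idw_predict(s, "Cd", c(250, 0)), 0.1, tolerance = 1e-12)
  expect_equal(idw_predict(s, "Cd", rbind(c(0, 0), c(1000, 0))), c(0, 1))
  one <- xy_survey(5, 5, 3.2)
  expect_equal(idw_predict(one, "Cd", rbind(c(0, 0), c(99, 99))), c(3.2, 3.2))
})

test_that("IDW predictions stay inside the data range", {
  s <- random_survey(25, seed = 3, noise = 0.5)
  tg <- withr::with_seed(4, cbind(runif(50, 0, 10000), runif(50, 0, 10000)))
  p <- idw_predict(s, "Cd", tg, p = 2, k = 10)
  expect_true(all(p >= min(s$Cd) - 1e-12 & p <= max(s$Cd) + 1e-12))
})

test_that("global polynomial recovers exact trends and flags degeneracy", {
  s <- random_survey(20, seed = 1, plane = c(1, 2e-3, 3e-3))
  tg <- rbind(c(100, 200), c(5000, 9000))
  expect_equal(gpi_fit_predict(s, "Cd", tg, degree = 1),
               1 + 2e-3 * tg[, 1] + 3e-3 * tg[, 2], tolerance = 1e-8)
  coll <- xy_survey(1:6 * 100, 1:6 * 100, 1:6)
  expect_error(gpi_fit_predict(coll, "Cd", c(0, 0), degree = 2), "rank")
})

test_that("quadratic surfaces are recovered by degree-2 GPI", {
  withr::with_seed(7, {
    x <- runif(25, 0, 1000); y <- runif(25, 0, 1000)
  })
  f <- function(x, y) 2 + 1e-3 * x - 2e-3 * y + 1e-6 * x^2 +
    2e-6 * x * y - 1e-6 * y^2
  s <- xy_survey(x, y, f(x, y))
  tg <- rbind(c(50, 50), c(900, 100), c(333, 777))
  expect_equal(gpi_fit_predict(s, "Cd", tg, degree = 2),
               f(tg[, 1], tg[, 2]), tolerance = 1e-8)
})

test_that("local polynomial equals a direct weighted solve", {
  s <- random_survey(7, seed = 5, side = 1000, noise = 0.3)
  x0 <- c(400, 600); bw <- 500
  got <- lpi_predict(s, "Cd", rbind(x0), bandwidth = bw)
  # independent weighted normal equations at the target
  d <- sqrt((s$x - x0[1])^2 + (s$y - x0[2])^2)
  w <- exp(-(d / bw)^2)
  X <- cbind(1, (s$x - x0[1]) / bw, (s$y - x0[2]) / bw)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * s$Cd))
  expect_equal(got, beta[1], tolerance = 1e-10)
})

test_that("local polynomial limits: exact on linear fields, global with wide kernels", {
  s <- random_survey(15, seed = 6, plane = c(2, 1e-3, -5e-4))
  tg <- rbind(c(1000, 2000), c(8000, 3000))
  expect_equal(lpi_predict(s, "Cd", tg, bandwidth = 5e3),
               2 + 1e-3 * tg[, 1] - 5e-4 * tg[, 2], tolerance = 1e-8)
  noisy <- random_survey(15, seed = 7, noise = 1)
  expect_equal(lpi_predict(noisy, "Cd", tg, bandwidth = 1e12),
               gpi_fit_predict(noisy, "Cd", tg, degree = 1), tolerance = 1e-8)
})

test_that("large ridge shrinks the local fit to the weighted mean", {
  s <- random_survey(10, seed = 8, side = 1000, noise = 1)
  x0 <- c(500, 500); bw <- 800
  got <- lpi_predict(s, "Cd", rbind(x0), bandwidth = bw, delta = 1e12)
  w <- exp(-((sqrt((s$x - x0[1])^2 + (s$y - x0[2])^2)) / bw)^2)
  expect_equal(got, sum(w * s$Cd) / sum(w), tolerance = 1e-6)
})

test_that("kernel smoothing reduces to LPI without barriers or ridge", {
  s <- random_survey(12, seed = 9, noise = 0.5)
  tg <- rbind(c(2000, 2000), c(7000, 1000))
  expect_identical(ks_predict(s, "Cd", tg, delta = 0),
                   lpi_predict(s, "Cd", tg, degree = 1, delta = 0))
  # with a barrier far away, distances are Euclidean and nothing changes
  far <- list(rbind(c(1e6, 1e6), c(1e6 + 10, 1e6)))
  expect_equal(ks_predict(s, "Cd", tg, delta = 1e-3, barriers = far),
               ks_predict(s, "Cd", tg, delta = 1e-3), tolerance = 1e-12)
})

test_that("RBF interpolation is exact and planar for three points", {
  s <- random_survey(20, seed = 10, noise = 1)
  at_stations <- rbf_fit_predict(s, "Cd", cbind(s$x, s$y))
  expect_lt(max(abs(at_stations - s$Cd)), 1e-6)
  for (kern in c("multiquadric", "inverse_multiquadric", "gaussian")) {
    p <- rbf_fit_predict(s, "Cd", cbind(s$x, s$y), kernel = kern)
    expect_lt(max(abs(p - s$Cd)), 1e-6)
  }
  # thin-plate spline through 3 non-collinear points is the unique plane
  tri <- xy_survey(c(0, 1000, 0), c(0, 0, 1000), c(1, 3, 5))
  plane <- function(x, y) 1 + 2e-3 * x + 4e-3 * y
  tg <- rbind(c(500, 500), c(250, 100), c(-200, 300))
  expect_equal(rbf_fit_predict(tri, "Cd", tg), plane(tg[, 1], tg[, 2]),
               tolerance = 1e-8)
})

test_that("interpolators are invariant to translation and station order", {
  s <- random_survey(15, seed = 12, noise = 0.7)
  tg <- rbind(c(4000, 4000), c(1000, 9000))
  sh <- s; sh$x <- sh$x + 5e4; sh$y <- sh$y - 2e4
  tgs <- tg + matrix(c(5e4, -2e4), 2, 2, byrow = TRUE)
  perm <- withr::with_seed(1, sample(nrow(s)))
  sp <- s[perm, ]
  for (spec in list(interp_spec("idw"), interp_spec("gpi"),
                    interp_spec("rbf"), interp_spec("lpi", bandwidth = 4000))) {
    base <- predict_points(spec, s, "Cd", tg)
    expect_equal(predict_points(spec, sh, "Cd", tgs), base, tolerance = 1e-6)
    expect_equal(predict_points(spec, sp, "Cd", tg), base, tolerance = 1e-8)
  }
})

test_that("grid prediction agrees with single-point calls", {
  s <- random_survey(20, seed = 13, noise = 0.5)
  g <- make_grid(s, cellsize = 2500)
  pg <- predict_grid(interp_spec("idw"), s, "Cd", g)
  cc <- grid_centers(g)
  cells <- withr::with_seed(2, sample(nrow(cc), 5))
  for (i in cells) {
    expect_equal(pg$values[cc$row[i], cc$col[i]],
                 idw_predict(s, "Cd", c(cc$x[i], cc$y[i])), tolerance = 1e-12)
  }
  expect_true(all(pg$values >= min(s$Cd) & pg$values <= max(s$Cd)))
  # a 1x1 grid is a point prediction
  g1 <- pred_grid(xll = 4975, yll = 4975, cellsize = 50, nrows = 1, ncols = 1)
  p1 <- predict_grid(interp_spec("idw"), s, "Cd", g1)
  expect_equal(p1$values[1, 1], idw_predict(s, "Cd", c(5000, 5000)))
})
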