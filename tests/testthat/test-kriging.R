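sph_gamma <- function(h, nug, ps, rg) {
  # independent spherical formula for the hand-assembled systems
  g <- ifelse(h < rg, ps * (1.5 * h / rg - 0.5 * (h / rg)^3), ps) + nug
  g[h == 0] <- 0
  g
}

test_that("ordinary kriging weights match an independent dense solve", {
  s <- xy_survey(c(0, 1200, 400), c(0, 300, 900), c(2.0, 3.5, 1.0))
  vm <- variogram_model("spherical", nugget = 0.1, psill = 1, range = 1500)
  x0 <- c(600, 400)
  res <- ok_predict(s, "Cd", vm, rbind(x0))
  # hand-assembled system [Gamma 1; 1' 0]
  D <- as.matrix(dist(cbind(s$x, s$y)))
  A <- rbind(cbind(sph_gamma(D, 0.1, 1, 1500), 1), c(1, 1, 1, 0))
  d0 <- sqrt((s$x - x0[1])^2 + (s$y - x0[2])^2)
  sol <- solve(A, c(sph_gamma(d0, 0.1, 1, 1500), 1))
  expect_equal(drop(attr(res, "weights")), unname(sol[1:3]),
               tolerance = 1e-10)
  expect_equal(res$pred, unname(sum(sol[1:3] * s$Cd)), tolerance = 1e-10)
  expect_equal(res$var,
               unname(sum(sol[1:3] * sph_gamma(d0, 0.1, 1, 1500)) + sol[4]),
               tolerance = 1e-10)
})

test_that("kriging weights always sum to one", {
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(10:40, 1))
    s <- random_survey(n, seed = seed, noise = 1)
    vm <- variogram_model("exponential", nugget = 0.05, psill = 1,
                          range = 3000)
    tg <- withr::with_seed(seed + 100,
                           cbind(runif(10, 0, 10000), runif(10, 0, 10000)))
    w_ok <- attr(ok_predict(s, "Cd", vm, tg), "weights")
    expect_lt(max(abs(colSums(w_ok) - 1)), 1e-10)
    w_uk <- attr(uk_predict(s, "Cd", vm, tg), "weights")
    expect_lt(max(abs(colSums(w_uk) - 1)), 1e-10)
  }
})

test_that("zero-nugget kriging reproduces station values; variance is valid", {
  s <- random_survey(20, seed = 31, noise = 0.8)
  vm <- variogram_model("spherical", nugget = 0, psill = 1, range = 4000)
  at <- cbind(s$x, s$y)
  res <- ok_predict(s, "Cd", vm, at, exact = FALSE)
  expect_lt(max(abs(res$pred - s$Cd)), 1e-6)
  expect_lt(max(abs(res$var)), 1e-6)
  tg <- withr::with_seed(1, cbind(runif(20, 0, 10000), runif(20, 0, 10000)))
  expect_true(all(ok_predict(s, "Cd", vm, tg)$var >= 0))
  # with nugget > 0 the at-station convention still returns measurements
  vm2 <- variogram_model("spherical", nugget = 0.3, psill = 1, range = 4000)
  expect_equal(ok_predict(s, "Cd", vm2, at)$pred, s$Cd)
  expect_gt(max(abs(ok_predict(s, "Cd", vm2, at, exact = FALSE)$pred - s$Cd)),
            1e-6)
})

test_that("single-station kriging is a constant surface", {
  s <- xy_survey(100, 100, 7.5)
  vm <- variogram_model("spherical", nugget = 0.1, psill = 1, range = 1000)
  res <- ok_predict(s, "Cd", vm, rbind(c(0, 0), c(500, 500)))
  expect_equal(res$pred, c(7.5, 7.5))
})

test_that("universal kriging captures a linear drift exactly", {
  s <- random_survey(15, seed = 33, plane = c(1, 2e-4, 3e-4))
  vm <- variogram_model("spherical", nugget = 0, psill = 0.5, range = 3000)
  tg <- rbind(c(-2000, 5000), c(12000, 1000), c(5000, 5000))
  res <- uk_predict(s, "Cd", vm, tg)
  expect_equal(res$pred, 1 + 2e-4 * tg[, 1] + 3e-4 * tg[, 2],
               tolerance = 1e-6)
  # constant drift reduces to ordinary kriging
  sn <- random_survey(15, seed = 34, noise = 1)
  ok <- ok_predict(sn, "Cd", vm, tg)
  uk <- uk_predict(sn, "Cd", vm, tg, drift = "constant")
  expect_equal(uk$pred, ok$pred, tolerance = 1e-10)
  expect_equal(uk$var, ok$var, tolerance = 1e-10)
})

test_that("collinear stations break linear drift identifiability", {
  s <- xy_survey(1:6 * 100, 1:6 * 100, rnorm(6))
  vm <- variogram_model("spherical", nugget = 0, psill = 1, range = 500)
  expect_error(uk_predict(s, "Cd", vm, c(0, 0)), "collinear")
})

test_that("coincident stations are reported for singular systems", {
  s <- xy_survey(c(0, 0, 500), c(0, 0, 500), c(1, 2, 3))
  vm <- variogram_model("spherical", nugget = 0, psill = 1, range = 1000)
  expect_error(ok_predict(s, "Cd", vm, c(100, 100), dedupe_tol = 0),
               "oincident")
  # with the default tolerance they are averaged instead
  expect_silent(ok_predict(s, "Cd", vm, c(100, 100)))
})

test_that("EBK with K = 1 is ordinary kriging under the base model", {
  s <- random_survey(20, seed = 35, noise = 0.6)
  tg <- rbind(c(3000, 3000), c(8000, 2000))
  eb <- ebk_predict(s, "Cd", tg, K = 1, seed = 4)
  base <- attr(eb, "base_model")
  ok <- ok_predict(s, "Cd", base, tg)
  expect_equal(eb$pred, ok$pred, tolerance = 1e-12)
  expect_equal(eb$var, ok$var, tolerance = 1e-12)
})

test_that("EBK is seed-deterministic and widens the variance", {
  s <- random_survey(25, seed = 36, noise = 0.8)
  tg <- withr::with_seed(3, cbind(runif(5, 0, 10000), runif(5, 0, 10000)))
  a <- ebk_predict(s, "Cd", tg, K = 8, seed = 9)
  b <- ebk_predict(s, "Cd", tg, K = 8, seed = 9)
  expect_identical(a$pred, b$pred)
  expect_identical(a$var, b$var)
  expect_equal(length(attr(a, "ensemble")), 8L)
  # variogram uncertainty: mixture variance >= single-model OK variance
  # on average over seeds
  diffs <- vapply(1:10, function(sd_) {
    xy <- withr::with_seed(sd_, matrix(runif(60, 0, 10000), 30, 2))
    z <- gaussian_random_field(
      xy, variogram_model("spherical", nugget = 0.1, psill = 1, range = 3000),
      seed = sd_)
    s2 <- xy_survey(xy[, 1], xy[, 2], z)
    eb <- ebk_predict(s2, "Cd", tg, K = 10, seed = sd_)
    ok <- ok_predict(s2, "Cd", attr(eb, "base_model"), tg)
    mean(eb$var - ok$var)
  }, 0)
  expect_gt(mean(diffs), 0)
})
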