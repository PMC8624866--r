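fast_pso <- function(seed = 1) {
  pso_config(n_particles = 6, n_iterations = 40, seed = seed)
}

test_that("zero auxiliary sites is the identity", {
  sim <- marinduque_sim(seed = 1)
  cfg <- hybrid_config("Cd", aux_sites = sim$aux, n_aux = 0,
                       pso = fast_pso())
  expect_identical(augment_with_nn(sim$survey, cfg), sim$survey)
  # and the hybrid CV path is then bit-identical to the plain one
  plain <- loocv(interp_spec("idw"), sim$survey, "Cd")
  hyb <- loocv(interp_spec("idw"), sim$survey, "Cd", hybrid = cfg)
  expect_identical(plain$mae, hyb$mae)
  expect_identical(plain$r, hyb$r)
})

test_that("densification appends seeded, reproducible pseudo-stations", {
  sim <- marinduque_sim(seed = 2)
  cfg <- hybrid_config("Cd", aux_sites = sim$aux, n_hidden = 5,
                       pso = fast_pso(2), lm_max_iter = 30,
                       lambda_pseudo = 0.5)
  a1 <- augment_with_nn(sim$survey, cfg)
  a2 <- augment_with_nn(sim$survey, cfg)
  expect_identical(a1$Cd, a2$Cd)
  expect_equal(nrow(a1), nrow(sim$survey) + nrow(sim$aux))
  expect_equal(sum(a1$is_pseudo), nrow(sim$aux))
  expect_true(all(a1$obs_weight[a1$is_pseudo] == 0.5))
  expect_true(all(a1$obs_weight[!a1$is_pseudo] == 1))
  expect_setequal(measured_stations(a1)$station_id, sim$survey$station_id)
})

test_that("strong covariate signal is recovered at auxiliary sites", {
  # noise-free field whose covariates are exact linear maps of the target
  spec <- field_spec(
    vm = variogram_model("spherical", nugget = 0.01, psill = 1,
                         range = 12000),
    link = list(temp = list(intercept = 30, slope = 5, noise_sd = 0),
                pH = list(intercept = 7, slope = -0.4, noise_sd = 0)),
    noise_sd = 0)
  st <- marinduque_stations()
  aux <- withr::with_seed(9, cbind(runif(25, min(st$x), max(st$x)),
                                   runif(25, min(st$y), max(st$y))))
  sim <- make_survey(spec, stations = st, aux_points = aux, seed = 3)
  cfg <- hybrid_config("Cd", covariates = c("x", "y", "temp", "pH"),
                       aux_sites = sim$aux, n_hidden = 8,
                       pso = pso_config(n_particles = 10, n_iterations = 150,
                                        seed = 3),
                       lm_max_iter = 150)
  aug <- augment_with_nn(sim$survey, cfg)
  pseudo <- aug[aug$is_pseudo, ]
  err <- mae(pseudo$Cd, sim$aux$truth)
  expect_lt(err, 0.05 * diff(range(sim$survey$Cd)))
})

test_that("auxiliary sites missing covariates are skipped or rejected", {
  sim <- marinduque_sim(seed = 4)
  aux <- sim$aux
  aux$temp[1:3] <- NA
  cfg <- hybrid_config("Cd", aux_sites = aux, n_hidden = 4,
                       pso = fast_pso(4), lm_max_iter = 20)
  expect_warning(aug <- augment_with_nn(sim$survey, cfg), "skipped")
  expect_equal(sum(aug$is_pseudo), nrow(aux) - 3)
  aux_all <- aux
  aux_all$temp <- NA
  cfg2 <- hybrid_config("Cd", aux_sites = aux_all, n_hidden = 4,
                        pso = fast_pso(4))
  expect_error(suppressWarnings(augment_with_nn(sim$survey, cfg2)), "skipped")
  no_cov <- sim$aux[, c("x", "y")]
  expect_error(hybrid_config("Cd", covariates = c("x", "y", "Cd")),
               "covariate")
  cfg3 <- hybrid_config("Cd", aux_sites = no_cov, n_hidden = 4,
                        pso = fast_pso(4))
  expect_error(augment_with_nn(sim$survey, cfg3), "lack covariate")
})

test_that("pseudo-stations never appear in held-out folds", {
  sim <- marinduque_sim(seed = 5)
  cfg <- hybrid_config("Cd", aux_sites = sim$aux, n_hidden = 4,
                       pso = fast_pso(5), lm_max_iter = 20)
  rep <- loocv(interp_spec("idw"), sim$survey, "Cd", hybrid = cfg)
  folds <- attr(rep, "folds")
  expect_false(any(grepl("PSEUDO", folds$station)))
  expect_equal(rep$n_folds, nrow(sim$survey))
})

test_that("hybrid grid interpolation densifies before prediction", {
  sim <- marinduque_sim(seed = 6)
  cfg <- hybrid_config("Cd", aux_sites = sim$aux, n_hidden = 4,
                       pso = fast_pso(6), lm_max_iter = 20)
  g <- make_grid(sim$survey, cellsize = 5000)
  hg <- hybrid_interpolate(interp_spec("idw"), sim$survey, cfg, g)
  aug <- augment_with_nn(sim$survey, cfg)
  pg <- predict_grid(interp_spec("idw"), aug, "Cd", g)
  expect_equal(hg$values, pg$values)
  # zero auxiliary points reduces to the plain grid bit-exactly
  cfg0 <- hybrid_config("Cd", aux_sites = sim$aux, n_aux = 0)
  expect_identical(hybrid_interpolate(interp_spec("idw"), sim$survey, cfg0, g),
                   predict_grid(interp_spec("idw"), sim$survey, "Cd", g))
})

test_that("method comparison reports a governing method deterministically", {
  sim <- marinduque_sim(seed = 7)
  cfg <- hybrid_config("Cd", aux_sites = sim$aux, n_hidden = 4,
                       pso = fast_pso(7), lm_max_iter = 20)
  cv1 <- run_method_comparison(sim$survey, "Cd", methods = "idw",
                               hybrid = NULL)
  expect_equal(nrow(cv1), 1)
  expect_equal(cv1$label, "IDW")
  cv <- run_method_comparison(sim$survey, "Cd",
                              methods = c("idw", "ok"), hybrid = cfg)
  expect_equal(nrow(cv), 4)
  expect_setequal(cv$label, c("IDW", "IDW+NN-PSO", "OK", "OK+NN-PSO"))
  expect_true(all(c("label", "method", "hybrid", "mae", "r") %in% names(cv)))
  g <- attr(cv, "governing")
  expect_equal(g$mae, min(cv$mae))
  cv2 <- run_method_comparison(sim$survey, "Cd",
                               methods = c("idw", "ok"), hybrid = cfg)
  expect_identical(cv$mae, cv2$mae)
  expect_s3_class(glance(cv), "tbl_df")
})
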