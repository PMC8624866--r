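# independent textbook formulas for the bias-corrected moments
oracle_skew <- function(x) {
  n <- length(x); s <- sd(x)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}
oracle_kurt <- function(x) {
  n <- length(x); s <- sd(x)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(((x - mean(x)) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

test_that("descriptive moments match the bias-corrected formulas", {
  x <- withr::with_seed(11, exp(rnorm(200)))
  s <- xy_survey(seq_along(x), seq_along(x), x, parameter = "Fe")
  d <- descriptive_stats(s, "Fe")
  expect_gt(d$skewness, 0)  # lognormal is right-skewed
  expect_equal(d$skewness, oracle_skew(x), tolerance = 1e-10)
  expect_equal(d$kurtosis, oracle_kurt(x), tolerance = 1e-10)
  expect_equal(d$cv_percent, 100 * sd(x) / mean(x), tolerance = 1e-12)
})

test_that("degenerate samples are handled explicitly", {
  s <- xy_survey(1:6, 1:6, rep(2, 6), parameter = "Zn")
  d <- descriptive_stats(s, "Zn")
  expect_equal(d$sd, 0)
  expect_equal(d$cv_percent, 0)
  expect_true(is.na(d$skewness) && is.na(d$kurtosis))
  sym <- xy_survey(1:9, 1:9, rep(c(-1, 0, 1), 3), parameter = "Zn")
  expect_equal(descriptive_stats(sym, "Zn")$skewness, 0)
  short <- xy_survey(1:3, 1:3, 1:3, parameter = "Zn")
  expect_error(descriptive_stats(short, "Zn"), "at least 4")
})

test_that("variability classes follow the printed CV bins", {
  expect_equal(as.character(classify_variability(c(10.30, 24.20, 88.40))),
               c("low", "intermediate", "high"))
  # boundaries: 15 is still low, 35 is already high
  expect_equal(as.character(classify_variability(c(15, 15.01, 35, 34.99))),
               c("low", "intermediate", "high", "intermediate"))
  expect_error(classify_variability(-1), "non-negative")
})

test_that("K-S normality verdicts separate normal from uniform samples", {
  p_norm <- vapply(1:20, function(sd_) {
    x <- withr::with_seed(sd_, rnorm(300))
    ks_normality(x)$p_value
  }, 0)
  expect_gt(median(p_norm), 0.05)
  x <- withr::with_seed(5, runif(300))
  expect_lt(ks_normality(x)$p_value, 0.05)
  expect_false(ks_normality(x)$normal_at_05)
  # the naive variant is exposed as an option
  expect_gt(ks_normality(withr::with_seed(2, rnorm(300)), "naive")$p_value, 0.05)
  expect_error(ks_normality(c(1, 2, 3, 4)), "at least 5")
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("correlation matrix matches direct formula with stars", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  s <- xy_survey(1:4, 1:4, x, parameter = "Cr")
  s$Pb <- y
  cm <- correlation_matrix(s, c("Cr", "Pb"))
  expect_equal(cm$r["Cr", "Cr"], 1)
  expect_equal(cm$r["Cr", "Pb"], 11 / sqrt(130), tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(cm$p >= 0 & cm$p <= 1, na.rm = TRUE))
  # p from t-distribution, checked against cor.test
  ct <- cor.test(x, y)
  expect_equal(cm$p["Cr", "Pb"], ct$p.value, tolerance = 1e-12)
  td <- tidy(cm)
  expect_equal(td$label[td$param1 == "Cr" & td$param2 == "Pb"], "very_strong")
})

test_that("correlation strength bins match the printed scheme", {
  expect_equal(as.character(classify_correlation(c(0.81, 0.05, -1, 0.95))),
               c("strong", "negligible", "very_strong", "very_strong"))
  # gap values go to the higher bin; lower edges are inclusive
  expect_equal(as.character(classify_correlation(c(0.39, 0.395, 0.895, 0.10))),
               c("weak", "moderate", "very_strong", "weak"))
  expect_equal(as.character(classify_correlation(c(0.69, 0.695, 0.70, 0.89))),
               c("moderate", "strong", "strong", "strong"))
  expect_error(classify_correlation(1.2), "<= 1")
})

test_that("guideline screening flags printed dry-season means correctly", {
  means <- tibble::tibble(
    station_id = "MEAN", lon = 121, lat = 13,
    pH = 7.02, EC = 935.17, TDS = 372.77,
    Cr = 0.06285, Cd = 0.03283, Fe = 2.92944, Mn = 0.71753,
    Ni = 0.03902, Pb = 0.05572, Zn = 4.32901, Cu = 0.12688)
  fl <- guideline_flags(as_survey(means))
  at <- function(p) fl[fl$parameter == p, ]
  expect_true(at("Cd")$exceeds_pnsdw)   # 0.03283 vs 0.003
  expect_true(at("Cr")$exceeds_pnsdw && at("Fe")$exceeds_pnsdw &&
                at("Pb")$exceeds_pnsdw)
  expect_false(at("Ni")$exceeds_pnsdw || at("Ni")$exceeds_who)
  expect_false(at("Cu")$exceeds_pnsdw)
  expect_false(at("pH")$exceeds_pnsdw)  # 7.02 inside 6.5-8.5
  expect_false(at("EC")$exceeds_who)    # 935.17 below 1500
  expect_true(at("Zn")$exceeds_who)     # 4.329 above the 3.0 WHO limit
  expect_false(at("Zn")$exceeds_pnsdw)  # but below the 5.0 PNSDW limit
})

test_that("unscreenable parameters are skipped with a warning", {
  s <- xy_survey(1:5, 1:5, 30 + 1:5, parameter = "temp")
  expect_warning(fl <- guideline_flags(s), "temp")
  expect_equal(nrow(fl), 0)
})
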