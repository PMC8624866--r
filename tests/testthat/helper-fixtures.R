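# Fixtures built in code: small planar surveys with known values.

# survey directly in projected coordinates (lon/lat are placeholders)
xy_survey <- function(x, y, z, parameter = "Cd", season = "dry") {
  df <- tibble::tibble(
    station_id = paste0("S", seq_along(x)),
    lon = 121 + x / 1e5, lat = 13 + y / 1e5,
    x = x, y = y, season = season
  )
  df[[parameter]] <- z
  as_survey(df)
}

# n random stations on a square domain, values from a plane + noise
random_survey <- function(n, seed, side = 10000, plane = c(1, 2e-4, -1e-4),
                          noise = 0, parameter = "Cd") {
  withr::with_seed(seed, {
    x <- runif(n, 0, side); y <- runif(n, 0, side)
    z <- plane[1] + plane[2] * x + plane[3] * y + rnorm(n, 0, noise)
  })
  xy_survey(x, y, z, parameter = parameter)
}

# small synthetic Marinduque-geometry survey with informative covariates
marinduque_sim <- function(seed, n_aux = 40, noise_sd = 0.05) {
  st <- marinduque_stations()
  gx <- seq(min(st$x), max(st$x), length.out = 8)
  gy <- seq(min(st$y), max(st$y), length.out = 8)
  aux <- as.matrix(expand.grid(x = gx, y = gy))
  keep <- withr::with_seed(seed + 1000, sample(nrow(aux), n_aux))
  make_survey(field_spec(noise_sd = noise_sd), stations = st,
              aux_points = aux[keep, ], seed = seed)
}

expect_tibble_row <- function(x) {
  expect_s3_class(x, "tbl_df")
  expect_equal(nrow(x), 1L)
}
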