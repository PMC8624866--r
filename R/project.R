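# WGS84 transverse Mercator (UTM) without external projection libraries.
# Forward map uses the Krueger series in conformal latitude (nanometer-level
# accuracy within a zone); the inverse is Newton iteration on the forward
# map, which makes forward/inverse a strict identity to solver tolerance.

.wgs84 <- list(a = 6378137.0, f = 1 / 298.257223563, k0 = 0.9996,
               false_easting = 5e5, false_northing_south = 1e7)

# forward Krueger series; lon/lat in degrees, returns easting/northing meters
tm_forward <- function(lon, lat, lon0) {
  a <- .wgs84$a; f <- .wgs84$f; k0 <- .wgs84$k0
  e <- sqrt(f * (2 - f))
  n <- f / (2 - f)
  A1 <- a / (1 + n) * (1 + n^2 / 4 + n^4 / 64)
  alpha <- c(n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16,
             13 * n^2 / 48 - 3 * n^3 / 5,
             61 * n^3 / 240)
  phi <- lat * pi / 180
  lam <- (lon - lon0) * pi / 180
  t <- sinh(atanh(sin(phi)) - e * atanh(e * sin(phi)))
  xi_p <- atan2(t, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  xi <- xi_p; eta <- eta_p
  for (j in 1:3) {
    xi <- xi + alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  list(x = .wgs84$false_easting + k0 * A1 * eta, y = k0 * A1 * xi)
}

tm_inverse <- function(x, y, lon0, tol = 1e-13, max_iter = 50) {
  lon <- rep(lon0, length(x))
  lat <- rep(0, length(x))
  # rough spherical initial guess
  lat <- y / 111194.9
  for (it in seq_len(max_iter)) {
    fw <- tm_forward(lon, lat, lon0)
    rx <- x - fw$x; ry <- y - fw$y
    if (max(abs(rx), abs(ry)) < 1e-9) break
    h <- 1e-7  # degrees, for the numerical Jacobian
    fx <- tm_forward(lon + h, lat, lon0)
    fy <- tm_forward(lon, lat + h, lon0)
    j11 <- (fx$x - fw$x) / h; j12 <- (fy$x - fw$x) / h
    j21 <- (fx$y - fw$y) / h; j22 <- (fy$y - fw$y) / h
    det <- j11 * j22 - j12 * j21
    lon <- lon + (j22 * rx - j12 * ry) / det
    lat <- lat + (-j21 * rx + j11 * ry) / det
  }
  list(lon = lon, lat = lat)
}

#' Project survey coordinates to UTM
#'
#' Fills the `x`/`y` columns with WGS84/UTM easting and northing in meters
#' (scale factor 0.9996, false easting 500 km). All interpolators treat
#' distances as planar Euclidean in these coordinates.
#'
#' @param s Survey tibble with `lon`/`lat` in decimal degrees.
#' @param zone UTM zone number (default 51, covering Marinduque).
#' @param hemisphere `"N"` or `"S"`.
#' @return The survey with `x` and `y` set.
#' @export
project_utm <- function(s, zone = 51, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  if (any(abs(s$lat) > 84)) abort("latitude outside +/-84 degrees")
  lon0 <- zone * 6 - 183
  fw <- tm_forward(s$lon, s$lat, lon0)
  s$x <- fw$x
  s$y <- fw$y + if (hemisphere == "S") .wgs84$false_northing_south else 0
  s
}

#' Inverse UTM projection
#'
#' @param x,y Easting/northing in meters.
#' @inheritParams project_utm
#' @return A tibble with `lon`, `lat` in decimal degrees.
#' @export
unproject_utm <- function(x, y, zone = 51, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  if (hemisphere == "S") y <- y - .wgs84$false_northing_south
  lon0 <- zone * 6 - 183
  inv <- tm_inverse(x, y, lon0)
  tibble(lon = inv$lon, lat = inv$lat)
}
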