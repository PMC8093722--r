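#' Transverse Mercator (UTM) projection for WGS84
#'
#' Forward and inverse Universal Transverse Mercator projection on the WGS84
#' ellipsoid, implemented with the 6th-order Krueger series. Accuracy is far
#' below 1 mm within a zone and its neighbours, which is ample for tracks
#' spanning a few kilometres.
#'
#' @param lon,lat numeric vectors of geographic coordinates in decimal degrees.
#' @param zone UTM zone number (1--60).
#' @param north logical; `TRUE` for the northern-hemisphere convention
#'   (false northing 0), `FALSE` adds 10,000,000 m.
#' @return `utm_forward()` returns a two-column matrix `x` (easting) and `y`
#'   (northing) in metres; `utm_inverse()` returns a matrix with columns
#'   `lon`, `lat` in decimal degrees.
#' @examples
#' xy <- utm_forward(34.1, 0.46, zone = 36)
#' ll <- utm_inverse(xy[, "x"], xy[, "y"], zone = 36)
#' @export
utm_forward <- function(lon, lat, zone, north = TRUE) {
  stopifnot(is.numeric(lon), is.numeric(lat), length(lon) == length(lat))
  if (!is.numeric(zone) || length(zone) != 1 || zone < 1 || zone > 60) {
    stop("`zone` must be a single UTM zone number in 1..60")
  }
  p <- .tm_constants()
  lon0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180 - lon0

  s <- sin(phi)
  # conformal latitude via the exact expression
  t <- sinh(atanh(s) - p$e * atanh(p$e * s))
  xi_p <- atan2(t, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))

  xi <- xi_p
  eta <- eta_p
  for (j in 1:6) {
    xi <- xi + p$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + p$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  x <- 500000 + p$k0 * p$A * eta
  y <- p$k0 * p$A * xi + if (north) 0 else 1e7
  cbind(x = x, y = y)
}

#' @rdname utm_forward
#' @param x,y numeric vectors of easting/northing in metres.
#' @export
utm_inverse <- function(x, y, zone, north = TRUE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (!is.numeric(zone) || length(zone) != 1 || zone < 1 || zone > 60) {
    stop("`zone` must be a single UTM zone number in 1..60")
  }
  p <- .tm_constants()
  lon0 <- (zone * 6 - 183) * pi / 180
  xi <- (y - if (north) 0 else 1e7) / (p$k0 * p$A)
  eta <- (x - 500000) / (p$k0 * p$A)

  xi_p <- xi
  eta_p <- eta
  for (j in 1:6) {
    xi_p <- xi_p - p$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - p$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  chi <- asin(sin(xi_p) / cosh(eta_p))  # conformal latitude
  phi <- chi
  for (j in 1:4) {
    phi <- phi + p$delta[j] * sin(2 * j * chi)
  }
  lam <- atan2(sinh(eta_p), cos(xi_p))
  cbind(lon = (lam + lon0) * 180 / pi, lat = phi * 180 / pi)
}

#' UTM zone containing a longitude
#'
#' @param lon longitude in decimal degrees.
#' @return integer zone number.
#' @export
utm_zone_for_lon <- function(lon) {
  as.integer(floor((lon + 180) / 6) %% 60 + 1)
}

# WGS84 Krueger-series constants, computed once
.tm_constants <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    a <- 6378137
    f <- 1 / 298.257223563
    n <- f / (2 - f)
    A <- a / (1 + n) * (1 + n^2 / 4 + n^4 / 64 + n^6 / 256)
    alpha <- c(
      n / 2 - 2 / 3 * n^2 + 5 / 16 * n^3 + 41 / 180 * n^4 - 127 / 288 * n^5 +
        7891 / 37800 * n^6,
      13 / 48 * n^2 - 3 / 5 * n^3 + 557 / 1440 * n^4 + 281 / 630 * n^5 -
        1983433 / 1935360 * n^6,
      61 / 240 * n^3 - 103 / 140 * n^4 + 15061 / 26880 * n^5 +
        167603 / 181440 * n^6,
      49561 / 161280 * n^4 - 179 / 168 * n^5 + 6601661 / 7257600 * n^6,
      34729 / 80640 * n^5 - 3418889 / 1995840 * n^6,
      212378941 / 319334400 * n^6
    )
    beta <- c(
      n / 2 - 2 / 3 * n^2 + 37 / 96 * n^3 - 1 / 360 * n^4 - 81 / 512 * n^5 +
        96199 / 604800 * n^6,
      1 / 48 * n^2 + 1 / 15 * n^3 - 437 / 1440 * n^4 + 46 / 105 * n^5 -
        1118711 / 3870720 * n^6,
      17 / 480 * n^3 - 37 / 840 * n^4 - 209 / 4480 * n^5 + 5569 / 90720 * n^6,
      4397 / 161280 * n^4 - 11 / 504 * n^5 - 830251 / 7257600 * n^6,
      4583 / 161280 * n^5 - 108847 / 3991680 * n^6,
      20648693 / 638668800 * n^6
    )
    # inverse conformal-latitude series (geodetic from conformal), O(n^5)
    delta <- c(
      2 * n - 2 / 3 * n^2 - 2 * n^3 + 116 / 45 * n^4,
      7 / 3 * n^2 - 8 / 5 * n^3 - 227 / 45 * n^4,
      56 / 15 * n^3 - 136 / 35 * n^4,
      4279 / 630 * n^4
    )
    cache <<- list(
      a = a, f = f, n = n, A = A, k0 = 0.9996,
      e = sqrt(f * (2 - f)), alpha = alpha, beta = beta, delta = delta
    )
    cache
  }
})
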