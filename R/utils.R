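# internal helpers shared across modules

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

EARTH_RADIUS_M <- 6371008.8

#' Project geographic coordinates to local planar meters
#'
#' Equirectangular projection about a reference point, adequate for survey
#' domains spanning a few degrees. `x` increases eastward, `y` northward.
#'
#' @param lon,lat numeric vectors of decimal degrees.
#' @param ref length-2 numeric `c(lon0, lat0)` reference point.
#' @return data.frame with columns `x`, `y` in meters.
#' @export
lonlat_to_xy <- function(lon, lat, ref) {
  lam0 <- ref[1] * pi / 180
  phi0 <- ref[2] * pi / 180
  data.frame(
    x = (lon * pi / 180 - lam0) * cos(phi0) * EARTH_RADIUS_M,
    y = (lat * pi / 180 - phi0) * EARTH_RADIUS_M
  )
}

#' Inverse of [lonlat_to_xy()]
#' @param x,y numeric vectors of local planar meters.
#' @param ref length-2 numeric `c(lon0, lat0)` reference point.
#' @return data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
xy_to_lonlat <- function(x, y, ref) {
  lam0 <- ref[1] * pi / 180
  phi0 <- ref[2] * pi / 180
  data.frame(
    lon = (lam0 + x / (cos(phi0) * EARTH_RADIUS_M)) * 180 / pi,
    lat = (phi0 + y / EARTH_RADIUS_M) * 180 / pi
  )
}

# Lambert azimuthal equal-area projection centered at (lon0, lat0), meters.
# Used for polygon areas: the projection preserves area exactly on the sphere.
laea_project <- function(lon, lat, lon0, lat0) {
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- lon0 * pi / 180; phi0 <- lat0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  kp <- sqrt(2 / denom)
  data.frame(
    x = EARTH_RADIUS_M * kp * cos(phi) * sin(lam - lam0),
    y = EARTH_RADIUS_M * kp * (cos(phi0) * sin(phi) -
                                 sin(phi0) * cos(phi) * cos(lam - lam0))
  )
}

# Shoelace formula; vertices in order, planar coordinates.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}
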