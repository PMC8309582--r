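#' Convert a gas mixing ratio in ppb to a mass concentration
#'
#' Converts parts-per-billion by volume to micrograms per cubic metre at
#' 1 atm and 20 degrees Celsius, via `ppb * 12.187 * M / 293` where `M` is
#' the molecular weight of the pollutant in g/mol (48 for ozone).
#'
#' @param ppb Numeric vector of mixing ratios (ppb), all non-negative.
#' @param molecular_weight Molecular weight in g/mol (default 48, ozone).
#' @return Numeric vector of concentrations in ug/m3.
#' @examples
#' ppb_to_ugm3(100)            # ozone
#' ppb_to_ugm3(50, molecular_weight = 46.01)  # NO2
#' @export
ppb_to_ugm3 <- function(ppb, molecular_weight = 48) {
  if (length(molecular_weight) != 1L || !is.finite(molecular_weight) ||
      molecular_weight <= 0) {
    stop_stkrige("stkrige_invalid_input", "'molecular_weight' must be a single positive number")
  }
  assert_finite(ppb, "ppb")
  if (any(ppb < 0)) {
    stop_stkrige("stkrige_invalid_input", "'ppb' must be non-negative")
  }
  ppb * 12.187 * molecular_weight / 293
}

.EARTH_RADIUS <- 6371000

#' Project WGS84 coordinates to local planar metres
#'
#' Azimuthal-equidistant projection on a spherical earth (radius
#' 6,371,000 m) centred at `origin`: the origin maps to (0, 0), `y` is
#' metres towards true north and `x` metres east. Pairwise distances
#' within ~20 km of the origin are accurate to far better than 0.1%,
#' which is all that city-scale variography needs.
#'
#' @param lat,lon Numeric vectors of coordinates in degrees.
#' @param origin Length-2 numeric `c(lat, lon)` of the local origin.
#' @return A data.frame with columns `x` and `y` in metres.
#' @seealso [local_to_wgs84()] for the inverse.
#' @export
project_to_local <- function(lat, lon, origin) {
  if (length(origin) != 2L || !all(is.finite(origin))) {
    stop_stkrige("stkrige_invalid_input", "'origin' must be finite c(lat, lon)")
  }
  assert_finite(lat, "lat"); assert_finite(lon, "lon")
  if (any(abs(lat) > 90) || abs(origin[1]) > 90) {
    stop_stkrige("stkrige_invalid_input", "latitude out of [-90, 90]")
  }
  if (any(abs(lon) > 180) || abs(origin[2]) > 180) {
    stop_stkrige("stkrige_invalid_input", "longitude out of [-180, 180]")
  }
  rad <- pi / 180
  phi0 <- origin[1] * rad; lam0 <- origin[2] * rad
  phi <- lat * rad; dlam <- lon * rad - lam0
  cospsi <- pmin(1, pmax(-1, sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)))
  psi <- acos(cospsi)
  az <- atan2(sin(dlam) * cos(phi),
              cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  data.frame(x = .EARTH_RADIUS * psi * sin(az), y = .EARTH_RADIUS * psi * cos(az))
}

#' Inverse of [project_to_local()]
#'
#' @param x,y Numeric vectors of local coordinates in metres.
#' @param origin Length-2 numeric `c(lat, lon)`.
#' @return A data.frame with columns `lat` and `lon` in degrees.
#' @export
local_to_wgs84 <- function(x, y, origin) {
  rad <- pi / 180
  phi0 <- origin[1] * rad; lam0 <- origin[2] * rad
  psi <- sqrt(x^2 + y^2) / .EARTH_RADIUS
  az <- atan2(x, y)
  phi <- asin(pmin(1, pmax(-1, sin(phi0) * cos(psi) + cos(phi0) * sin(psi) * cos(az))))
  lam <- lam0 + atan2(sin(az) * sin(psi) * cos(phi0), cos(psi) - sin(phi0) * sin(phi))
  data.frame(lat = phi / rad, lon = lam / rad)
}
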