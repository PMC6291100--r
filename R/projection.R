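## Local tangent-plane projection. Tracks span a few km at most, so a
## plate-carree plane scaled by cos(lat0) at the track centroid is accurate to
## well under a centimetre over 10 km, and is exactly invertible.

EARTH_RADIUS_M <- 6378137

#' Project geographic coordinates onto a local planar frame
#'
#' Converts WGS84 longitude/latitude to metres in a tangent plane centred on
#' `origin` (by default the centroid of the input points). The mapping is
#' linear in the angular offsets, so [unproject_xy()] inverts it exactly.
#'
#' @param lon,lat Numeric vectors of degrees (WGS84).
#' @param origin Length-2 numeric `c(lon0, lat0)` in degrees, or `NULL` to use
#'   the centroid of the inputs.
#' @return A tibble with columns `x`, `y` (metres) carrying the origin as the
#'   `"origin"` attribute.
#' @seealso [unproject_xy()]
#' @export
#' @examples
#' project_lonlat(c(-76, -76.001), c(4.9, 4.9))
project_lonlat <- function(lon, lat, origin = NULL) {
  stopifnot(length(lon) == length(lat))
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  rad <- pi / 180
  x <- EARTH_RADIUS_M * cos(origin[2] * rad) * (lon - origin[1]) * rad
  y <- EARTH_RADIUS_M * (lat - origin[2]) * rad
  out <- tibble::tibble(x = x, y = y)
  attr(out, "origin") <- origin
  out
}

#' Invert the local planar projection
#'
#' @param x,y Numeric vectors of metres in the frame defined by `origin`.
#' @param origin Length-2 numeric `c(lon0, lat0)` in degrees.
#' @return A tibble with columns `lon`, `lat` in degrees.
#' @seealso [project_lonlat()]
#' @export
unproject_xy <- function(x, y, origin) {
  rad <- pi / 180
  lon <- origin[1] + x / (EARTH_RADIUS_M * cos(origin[2] * rad)) / rad
  lat <- origin[2] + y / EARTH_RADIUS_M / rad
  tibble::tibble(lon = lon, lat = lat)
}
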