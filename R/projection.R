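#' Equal-area azimuthal projection specification
#'
#' Defines a spherical Lambert azimuthal equal-area (LAEA) projection centred
#' on an arbitrary point, with output in kilometres. The south-polar aspect
#' used for Patagonian-shelf work is obtained with `center_lat = -90`;
#' oblique aspects (handy for desk-scale synthetic regions) are supported by
#' the same closed forms.
#'
#' @param center_lon,center_lat projection centre in decimal degrees.
#' @param radius_km sphere radius; default is the IUGG mean Earth radius.
#' @return an object of class `"laea_projection"`.
#' @examples
#' sp <- proj_spec(-65, -90)
#' xy <- project(cbind(-65, -50), sp)
#' lonlat <- unproject(xy, sp)
#' @export
proj_spec <- function(center_lon, center_lat, radius_km = 6371.0088) {
  stopifnot(is.finite(center_lon), is.finite(center_lat),
            center_lat >= -90, center_lat <= 90, radius_km > 0)
  structure(list(center_lon = center_lon, center_lat = center_lat,
                 radius_km = radius_km),
            class = "laea_projection")
}

#' @export
print.laea_projection <- function(x, ...) {
  cat(sprintf("Lambert azimuthal equal-area projection (spherical)\n  centre: %.4f, %.4f deg\n  radius: %.4f km\n",
              x$center_lon, x$center_lat, x$radius_km))
  invisible(x)
}

.deg2rad <- pi / 180

#' Forward equal-area projection
#'
#' Projects longitude/latitude points (WGS84 degrees, treated spherically) to
#' planar kilometres. The projection is exactly area-preserving on the sphere;
#' the centre maps to the origin. The antipode of the projection centre is the
#' one singular point and is rejected.
#'
#' @param lonlat two-column matrix or data.frame (lon, lat) in degrees.
#' @param spec a [proj_spec()] object.
#' @return matrix with columns `x`, `y` in km.
#' @export
project <- function(lonlat, spec) {
  stopifnot(inherits(spec, "laea_projection"))
  ll <- as.matrix(lonlat)
  if (ncol(ll) < 2) stop("lonlat must have two columns (lon, lat)")
  lon <- ll[, 1] * .deg2rad
  lat <- ll[, 2] * .deg2rad
  if (any(abs(ll[, 2]) > 90 + 1e-12)) stop("latitudes must lie in [-90, 90]")
  lam0 <- spec$center_lon * .deg2rad
  phi0 <- spec$center_lat * .deg2rad
  # cosine of angular distance from the centre; antipode has c == -1
  cosc <- sin(phi0) * sin(lat) + cos(phi0) * cos(lat) * cos(lon - lam0)
  if (any(cosc < -1 + 1e-12))
    stop("points antipodal to the projection centre cannot be projected")
  kp <- sqrt(2 / (1 + cosc))
  x <- spec$radius_km * kp * cos(lat) * sin(lon - lam0)
  y <- spec$radius_km * kp *
    (cos(phi0) * sin(lat) - sin(phi0) * cos(lat) * cos(lon - lam0))
  cbind(x = x, y = y)
}

#' Inverse equal-area projection
#'
#' @param xy two-column matrix (x, y) in km as produced by [project()].
#' @param spec a [proj_spec()] object.
#' @return matrix with columns `lon`, `lat` in degrees.
#' @export
unproject <- function(xy, spec) {
  stopifnot(inherits(spec, "laea_projection"))
  m <- as.matrix(xy)
  x <- m[, 1] / spec$radius_km
  y <- m[, 2] / spec$radius_km
  lam0 <- spec$center_lon * .deg2rad
  phi0 <- spec$center_lat * .deg2rad
  rho <- sqrt(x^2 + y^2)
  # rho = 2 sin(c/2) where c is angular distance from centre
  c_ang <- 2 * asin(pmin(1, rho / 2))
  lat <- ifelse(rho < 1e-15, phi0,
                asin(cos(c_ang) * sin(phi0) +
                       y * sin(c_ang) * cos(phi0) / pmax(rho, 1e-300)))
  lon <- ifelse(rho < 1e-15, lam0,
                lam0 + atan2(x * sin(c_ang),
                             rho * cos(phi0) * cos(c_ang) -
                               y * sin(phi0) * sin(c_ang)))
  lon <- (lon + pi) %% (2 * pi) - pi
  cbind(lon = lon / .deg2rad, lat = lat / .deg2rad)
}
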