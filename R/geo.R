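#' Geographic point
#'
#' Lightweight latitude/longitude pair used for release sites, track
#' endpoints and destination points. Longitudes are normalised to
#' (-180, 180].
#'
#' @param lat Latitude in decimal degrees, in \[-90, 90\].
#' @param lon Longitude in decimal degrees; any value is accepted and
#'   wrapped into (-180, 180].
#'
#' @return An object of class `geo_point`: a named list with elements
#'   `lat` and `lon`.
#' @examples
#' geo_point(55.15, 20.86)
#' @export
geo_point <- function(lat, lon) {
  if (!is.numeric(lat) || !is.numeric(lon) || length(lat) != 1L || length(lon) != 1L) {
    abort("`lat` and `lon` must be single numeric values.")
  }
  if (is.na(lat) || is.na(lon)) abort("`lat` and `lon` must not be NA.")
  if (lat < -90 || lat > 90) abort("`lat` must lie in [-90, 90].")
  structure(list(lat = lat, lon = wrap_lon(lon)), class = "geo_point")
}

#' @export
print.geo_point <- function(x, ...) {
  cat(sprintf("<geo_point> %.5f°%s, %.5f°%s\n",
              abs(x$lat), if (x$lat >= 0) "N" else "S",
              abs(x$lon), if (x$lon >= 0) "E" else "W"))
  invisible(x)
}

#' Study release sites
#'
#' Coordinates of the two release sites of the displacement design the
#' synthetic generator emulates: the trapping/control-release site at
#' Rybachy on the Courish Spit and the displaced-release site near Kazan,
#' about 1,750 km (great circle) to the east.
#'
#' @return A named list of two [geo_point()] objects, `rybachy` and `kazan`.
#' @examples
#' gc_distance(release_sites()$rybachy, release_sites()$kazan)
#' @export
release_sites <- function() {
  list(
    rybachy = geo_point(55 + 9 / 60 + 13 / 3600, 20 + 51 / 60 + 29 / 3600),
    kazan   = geo_point(55 + 51 / 60 + 18 / 3600, 48 + 48 / 60 + 18 / 3600)
  )
}

#' Wrap longitudes into (-180, 180]
#'
#' @param lon_deg Numeric vector of longitudes in degrees.
#' @return Wrapped longitudes, west negative.
#' @examples
#' wrap_lon(c(357, -181, 180.5))
#' @export
wrap_lon <- function(lon_deg) {
  w <- ((lon_deg + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Wrap bearings into \[0, 360)
#'
#' @param bearing_deg Numeric vector of bearings in degrees.
#' @return Bearings wrapped into \[0, 360), 0 = north, 90 = east.
#' @export
wrap_bearing <- function(bearing_deg) bearing_deg %% 360

# Coerce a geo_point / list / data frame / matrix to an n x 2 (lon, lat)
# matrix as geosphere expects.
as_lonlat <- function(p) {
  if (inherits(p, "geo_point")) return(cbind(p$lon, p$lat))
  if (is.data.frame(p) || is.list(p)) {
    if (!all(c("lat", "lon") %in% names(p))) {
      abort("Points must have `lat` and `lon` components.")
    }
    return(cbind(p$lon, p$lat))
  }
  if (is.matrix(p) && ncol(p) == 2L) return(p[, 2:1, drop = FALSE]) # assume (lat, lon)
  abort("Cannot interpret point input; use geo_point() or a lat/lon data frame.")
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km. Accepts single
#' [geo_point()]s or lat/lon data frames (recycled row-wise).
#'
#' @param a,b Points: [geo_point()] objects or data frames with `lat` and
#'   `lon` columns in decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' s <- release_sites()
#' gc_distance(s$rybachy, s$kazan) # ~1750 km
#' @export
gc_distance <- function(a, b) {
  geosphere::distHaversine(as_lonlat(a), as_lonlat(b), r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial great-circle bearing
#'
#' Bearing of the great circle from `a` towards `b` at `a`, in degrees
#' clockwise from north, in \[0, 360).
#'
#' @inheritParams gc_distance
#' @return Bearing(s) in degrees. Coincident points raise an error (the
#'   bearing is undefined there).
#' @examples
#' s <- release_sites()
#' initial_bearing(s$rybachy, s$kazan) # eastward, ~76 degrees
#' @export
initial_bearing <- function(a, b) {
  pa <- as_lonlat(a)
  pb <- as_lonlat(b)
  same <- rowSums(abs(pa - pb) < 1e-12) == 2L
  if (any(same)) abort("Initial bearing is undefined for coincident points.")
  # f = 0: spherical bearing, consistent with the haversine distance and
  # the spherical destination point
  wrap_bearing(geosphere::bearing(pa, pb, a = EARTH_RADIUS_KM * 1000, f = 0))
}

#' Destination point along a great circle
#'
#' Point reached by travelling `distance_km` from `start` on the initial
#' bearing `bearing_deg`, on the 6371-km sphere.
#'
#' @param start A [geo_point()] (or lat/lon data frame).
#' @param bearing_deg Initial bearing in degrees (0 = north).
#' @param distance_km Non-negative distance in kilometres.
#' @return A [geo_point()] if the inputs describe a single movement,
#'   otherwise a tibble with `lat` and `lon` columns.
#' @export
destination_point <- function(start, bearing_deg, distance_km) {
  if (any(distance_km < 0)) abort("`distance_km` must be non-negative.")
  d <- geosphere::destPoint(as_lonlat(start), bearing_deg, distance_km * 1000,
                            r = EARTH_RADIUS_KM * 1000)
  if (nrow(d) == 1L) {
    geo_point(d[1, 2], d[1, 1])
  } else {
    tibble::tibble(lat = d[, 2], lon = wrap_lon(d[, 1]))
  }
}
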