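# Builders for small in-code fixtures shared across test files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A positions tibble from parallel vectors, with sensible defaults.
make_positions <- function(times, lat, lon, quality = "3", sensor = "doppler") {
  tibble::tibble(
    timestamp = utc(times),
    lat = lat, lon = lon,
    quality = rep_len(quality, length(lat)),
    sensor = rep_len(sensor, length(lat))
  )
}

# A track running due south along a meridian: one fix per day, displacement
# steps_km[i] between fix i and i+1.
make_meridional_track <- function(steps_km, start_lat = 55, lon = 21,
                                  bird_id = "b1", quality = "3", ...) {
  lat <- start_lat - c(0, cumsum(steps_km)) / 111.19493
  times <- utc("2016-08-01 12:00:00") + 86400 * (seq_along(lat) - 1)
  track(bird_id, make_positions(times, lat, rep(lon, length(lat)), quality = quality),
        release_site = geo_point(start_lat, lon), ...)
}

# Write a minimal Movebank-dialect CSV and return its path.
write_movebank_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path, progress = FALSE)
  path
}

movebank_rows <- function(id, times, lat, lon, lc = "3",
                          sensor = "argos-doppler-shift") {
  tibble::tibble(
    `individual-local-identifier` = id,
    timestamp = times,
    `location-lat` = lat,
    `location-long` = lon,
    `argos:lc` = rep_len(lc, length(lat)),
    `sensor-type` = rep_len(sensor, length(lat))
  )
}

# Metrics-table fixture for the comparison stage.
make_metrics <- function(group, lon_displacement,
                         age = "juvenile",
                         endpoint_bearing = NULL,
                         doy_500 = NA_integer_) {
  n <- length(lon_displacement)
  tibble::tibble(
    bird_id = sprintf("bird%02d", seq_len(n)),
    age = rep_len(age, n),
    group = rep_len(group, n),
    year = 2016L,
    lon_displacement = lon_displacement,
    endpoint_bearing = endpoint_bearing %||% (180 + lon_displacement),
    doy_500 = rep_len(doy_500, n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
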