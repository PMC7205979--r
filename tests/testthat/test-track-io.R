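test_that("a small CSV reads into one sorted track, class Z retained", {
  rows <- movebank_rows("cu01",
                        c("2016-08-03 11:00:00", "2016-08-01 10:00:00", "2016-08-02 09:30:00"),
                        lat = c(53, 55, 54), lon = c(21, 21, 21),
                        lc = c("3", "Z", "1"))
  path <- write_movebank_csv(rows)
  tracks <- read_tracks(path, quiet = TRUE)
  expect_length(tracks, 1)
  trk <- tracks[["cu01"]]
  expect_s3_class(trk, "track")
  expect_equal(n_positions(trk), 3)
  # sorted ascending regardless of file order
  expect_false(is.unsorted(trk$positions$timestamp, strictly = TRUE))
  expect_equal(trk$positions$lat, c(55, 54, 53))
  # filtering is a separate step: the Z row is still present after reading
  expect_true("Z" %in% as.character(trk$positions$quality))
})

test_that("unparsable rows are dropped and counted; missing columns error", {
  rows <- movebank_rows("cu01", c("2016-08-01 10:00:00", "not-a-time", "2016-08-03 10:00:00"),
                        lat = c(55, 54, NA), lon = c(21, 21, 21))
  path <- write_movebank_csv(rows)
  expect_message(tracks <- read_tracks(path), "dropped 2 of 3")
  expect_equal(n_positions(tracks[[1]]), 1)

  bad <- rows[, setdiff(names(rows), "location-lat")]
  expect_error(read_tracks(write_movebank_csv(bad), quiet = TRUE), "location-lat")
})

test_that("an empty file yields an empty collection with a warning", {
  path <- write_movebank_csv(movebank_rows(character(0), character(0),
                                           numeric(0), numeric(0)))
  expect_warning(tracks <- read_tracks(path), "no data rows")
  expect_length(tracks, 0)
})

test_that("metadata attaches cohort labels and release sites", {
  rows <- movebank_rows("cu01", c("2016-08-01 10:00:00", "2016-08-02 10:00:00"),
                        lat = c(55.9, 55.0), lon = c(48.8, 48.5))
  meta <- tibble::tibble(bird_id = "cu01", age = "juvenile", group = "displaced",
                         year = 2016, release_lat = 55.855, release_lon = 48.805)
  trk <- read_tracks(write_movebank_csv(rows), metadata = meta, quiet = TRUE)[[1]]
  expect_equal(trk$age, "juvenile")
  expect_equal(trk$group, "displaced")
  expect_equal(trk$release_site$lat, 55.855)
})

test_that("quality filtering removes exactly class Z and is idempotent", {
  trk <- make_meridional_track(c(100, 120), quality = c("3", "Z", "B"))
  f1 <- filter_quality(trk)
  expect_equal(as.character(f1$positions$quality), c("3", "B"))
  expect_identical(filter_quality(f1)$positions, f1$positions) # idempotent
  clean <- make_meridional_track(c(100, 120), quality = "2")
  expect_identical(filter_quality(clean)$positions, clean$positions) # no-op
  allz <- make_meridional_track(c(100, 120), quality = "Z")
  expect_warning(fz <- filter_quality(allz), "class Z")
  expect_equal(n_positions(fz), 0)
})

test_that("duty-cycle selection takes the best class, noon breaking ties", {
  # quality dominates: class 3 at 18:00 beats class 1 at 11:00
  trk <- track("b1", make_positions(c("2016-08-01 11:00:00", "2016-08-01 18:00:00"),
                                    lat = c(55, 54.9), lon = c(21, 21),
                                    quality = c("1", "3")))
  sel <- select_duty_cycle_positions(trk, 58)
  expect_equal(n_positions(sel), 1)
  expect_equal(as.character(sel$positions$quality), "3")
  expect_equal(format(sel$positions$timestamp, "%H"), "18")

  # equal class: 13:00 is closer to 12:00 UTC than 10:00
  trk2 <- track("b2", make_positions(c("2016-08-01 10:00:00", "2016-08-01 13:00:00"),
                                     lat = c(55, 54.9), lon = c(21, 21),
                                     quality = "3"))
  sel2 <- select_duty_cycle_positions(trk2, 58)
  expect_equal(format(sel2$positions$timestamp, "%H"), "13")

  # single fix is returned unchanged
  single <- track("b3", make_positions("2016-08-01 10:00:00", 55, 21))
  expect_identical(select_duty_cycle_positions(single, 58)$positions, single$positions)
})

test_that("duty-cycle selection never increases counts nor reorders time", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    times <- utc("2016-08-01") + sort(sample.int(30 * 86400, n))
    trk <- track("p", make_positions(times, runif(n, 40, 60), runif(n, 10, 50),
                                     quality = sample(c("3", "2", "1", "0", "A", "B"),
                                                      n, replace = TRUE)))
    for (cyc in c(24, 58, 100)) {
      sel <- select_duty_cycle_positions(trk, cyc)
      expect_lte(n_positions(sel), n_positions(trk))
      expect_false(is.unsorted(sel$positions$timestamp, strictly = TRUE))
      # at most one fix per window
      w <- floor(as.numeric(difftime(sel$positions$timestamp,
                                     trk$positions$timestamp[1], units = "hours")) / cyc)
      expect_false(anyDuplicated(w) > 0)
    }
  }
})

test_that("CSV write/read round trip preserves retained fields", {
  t1 <- make_meridional_track(c(150, 200), bird_id = "cu01",
                              age = "juvenile", group = "control", year = 2016L)
  t2 <- make_meridional_track(c(90, 300), start_lat = 55.8, lon = 48.8,
                              bird_id = "cu02", age = "adult", group = "displaced",
                              year = 2017L)
  path <- tempfile(fileext = ".csv")
  write_tracks(list(cu01 = t1, cu02 = t2), path, format = "csv")
  back <- read_tracks(path, quiet = TRUE)
  expect_setequal(names(back), c("cu01", "cu02"))
  for (nm in c("cu01", "cu02")) {
    orig <- if (nm == "cu01") t1 else t2
    got <- back[[nm]]
    expect_identical(got$positions$timestamp, orig$positions$timestamp)
    expect_equal(got$positions$lat, orig$positions$lat, tolerance = 1e-6)
    expect_equal(got$positions$lon, orig$positions$lon, tolerance = 1e-6)
    expect_identical(as.character(got$positions$quality),
                     as.character(orig$positions$quality))
    expect_identical(got$age, orig$age)
    expect_identical(got$group, orig$group)
    expect_identical(got$year, orig$year)
    expect_equal(got$release_site$lat, orig$release_site$lat, tolerance = 1e-6)
  }
})

test_that("GeoJSON output is one LineString per bird with [lon, lat] order", {
  t1 <- make_meridional_track(c(150, 200), bird_id = "cu01", lon = 21)
  path <- tempfile(fileext = ".geojson")
  write_tracks(list(t1), path, format = "geojson")
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 1)
  feat <- gj$features[[1]]
  expect_equal(feat$geometry$type, "LineString")
  expect_equal(feat$properties$bird_id, "cu01")
  first <- unlist(feat$geometry$coordinates[[1]])
  expect_equal(first, c(21, 55), tolerance = 1e-9) # lon first
  expect_error(write_tracks(list(), tempfile(), "geojson"), "empty")
})
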