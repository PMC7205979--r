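test_that("step extraction keeps strictly-over-threshold movements", {
  trk <- make_meridional_track(c(50, 150, 120))
  steps <- extract_steps(trk, min_step_km = 100)
  expect_equal(nrow(steps), 2)
  expect_true(all(steps$gc_length_km > 100))
  expect_true(all(steps$dlat < 0)) # southbound
  expect_equal(steps$dlon, c(0, 0))

  # a movement exactly at the threshold is excluded (strict inequality)
  single <- make_meridional_track(130)
  d <- gc_distance(geo_point(55, 21),
                   geo_point(single$positions$lat[2], single$positions$lon[2]))
  expect_error(extract_steps(single, min_step_km = d), "No movement")
  # and nothing at all long enough errors
  expect_error(extract_steps(make_meridional_track(c(40, 60)), min_step_km = 100),
               "No movement")
})

test_that("simulated endpoint clouds have the configured size and determinism", {
  set.seed(7)
  trks <- lapply(1:3, function(i) make_meridional_track(runif(8, 110, 400),
                                                        bird_id = paste0("b", i)))
  steps <- extract_steps(trks)
  cloud <- simulate_endpoints(steps, seed = 42)
  expect_equal(nrow(cloud), 15000)
  expect_equal(sort(unique(cloud$k)), 1:15)
  expect_true(all(table(cloud$k) == 1000))
  cloud2 <- simulate_endpoints(steps, seed = 42)
  expect_identical(tibble::as_tibble(cloud), tibble::as_tibble(cloud2))
  cloud3 <- simulate_endpoints(steps, seed = 43)
  expect_false(identical(cloud$dlat, cloud3$dlat)) # meridional steps: dlat varies
})

test_that("a one-step set gives exactly k times that step", {
  one <- tibble::tibble(dlon = -1.25, dlat = -2.5)
  cloud <- simulate_endpoints(one, k_min = 1, k_max = 5, tracks_per_k = 10, seed = 1)
  expect_equal(cloud$dlon, cloud$k * -1.25)
  expect_equal(cloud$dlat, cloud$k * -2.5)
})

test_that("per-k endpoint means follow linearity of expectation", {
  set.seed(17)
  steps <- tibble::tibble(dlon = rnorm(30, -0.8, 0.5), dlat = rnorm(30, -2, 0.6))
  cloud <- simulate_endpoints(steps, seed = 3)
  for (k in c(1, 5, 15)) {
    sub <- cloud[cloud$k == k, ]
    tol <- 3 * stats::sd(sub$dlon) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$dlon) - k * mean(steps$dlon)), tol)
    expect_lt(abs(mean(sub$dlat) - k * mean(steps$dlat)),
              3 * stats::sd(sub$dlat) / sqrt(nrow(sub)))
  }
})

test_that("resampled endpoint frequencies match exhaustive enumeration", {
  # |S| = 3 steps, k = 2: 9 equally likely ordered sums
  steps <- tibble::tibble(dlon = c(-1, 0, 2), dlat = c(-2, -1, -3))
  for (k in 2:3) {
    n_sim <- 9000
    cloud <- simulate_endpoints(steps, k_min = k, k_max = k,
                                tracks_per_k = n_sim, seed = 5 + k)
    # enumerate all |S|^k ordered selections
    grids <- do.call(expand.grid, rep(list(1:3), k))
    exact <- table(apply(grids, 1, function(ix) sum(steps$dlon[ix]))) / 3^k
    got <- table(factor(round(cloud$dlon, 9),
                        levels = as.character(sort(unique(round(
                          apply(grids, 1, function(ix) sum(steps$dlon[ix])), 9)))))) / n_sim
    for (v in names(exact)) {
      p <- exact[[v]]
      se <- sqrt(p * (1 - p) / n_sim)
      expect_lt(abs(got[[v]] - p), 3 * se + 1e-9)
    }
  }
})

test_that("independent-axis resampling breaks the lon/lat pairing", {
  steps <- tibble::tibble(dlon = c(-5, 5), dlat = c(-5, 5)) # perfectly correlated
  paired <- simulate_endpoints(steps, k_min = 1, k_max = 1,
                               tracks_per_k = 2000, seed = 9)
  expect_true(all(paired$dlon == paired$dlat))
  indep <- simulate_endpoints(steps, k_min = 1, k_max = 1,
                              tracks_per_k = 2000, seed = 9, pair_axes = FALSE)
  expect_false(all(indep$dlon == indep$dlat))
})

test_that("compensation calls follow the quantile/direction contract", {
  set.seed(23)
  cloud <- simulate_endpoints(tibble::tibble(dlon = rnorm(40, 0, 1),
                                             dlat = rnorm(40, -2, 0.5)), seed = 31)
  med <- stats::median(cloud$dlon)
  far_west <- min(cloud$dlon) - 5
  far_east <- max(cloud$dlon) + 5
  obs <- tibble::tibble(bird_id = c("mid", "west", "east"),
                        dlon = c(med, far_west, far_east),
                        dlat = c(-20, -20, -20))
  calls <- classify_compensation(cloud, obs, compensation_sign = "westward")
  expect_equal(calls$level[calls$bird_id == "mid"], "ns")
  expect_false(calls$compensating[calls$bird_id == "mid"])
  expect_equal(calls$level[calls$bird_id == "west"], "p<0.001")
  expect_true(calls$compensating[calls$bird_id == "west"])
  expect_equal(calls$direction[calls$bird_id == "west"], "toward_control_route")
  # equally extreme the other way is significant but not compensation
  expect_equal(calls$level[calls$bird_id == "east"], "p<0.001")
  expect_false(calls$compensating[calls$bird_id == "east"])
  expect_equal(calls$direction[calls$bird_id == "east"], "away")
  # with an eastward compensation sign the roles swap
  calls_e <- classify_compensation(cloud, obs, compensation_sign = "eastward")
  expect_true(calls_e$compensating[calls_e$bird_id == "east"])
  expect_false(calls_e$compensating[calls_e$bird_id == "west"])
})

test_that("an empty latitude band falls back to the pooled cloud", {
  cloud <- simulate_endpoints(tibble::tibble(dlon = c(-1, 1), dlat = c(-2, -1)),
                              k_min = 1, k_max = 2, tracks_per_k = 50, seed = 2)
  obs <- tibble::tibble(bird_id = "b", dlon = 0, dlat = -50)
  expect_warning(calls <- classify_compensation(cloud, obs, lat_band_deg = 1),
                 "full cloud")
  expect_equal(calls$n_reference, nrow(cloud))
  # a usable band restricts the reference set
  obs2 <- tibble::tibble(bird_id = "b", dlon = 0, dlat = -2)
  calls2 <- classify_compensation(cloud, obs2, lat_band_deg = 0.5)
  expect_lt(calls2$n_reference, nrow(cloud))
})

test_that("null contours are symmetric for mirror-image steps and widen with level", {
  set.seed(29)
  base <- tibble::tibble(dlon = runif(20, 0.2, 2), dlat = runif(20, -3, -1))
  mirrored <- dplyr::bind_rows(base, dplyr::mutate(base, dlon = -dlon))
  cloud <- simulate_endpoints(mirrored, seed = 37)
  env <- null_contours(cloud, levels = c(0.05, 0.001), lat_bin_deg = 5)
  good <- env[env$reliable & env$level == 0.05, ]
  # symmetric about dlon = 0 within Monte-Carlo error
  expect_lt(stats::median(abs(good$lower + good$upper)), 1)
  # the stricter level gives wider envelopes in every shared bin
  e05 <- env[env$level == 0.05, ]
  e001 <- env[env$level == 0.001, ]
  shared <- intersect(e05$lat_mid, e001$lat_mid)
  expect_true(all(e001$upper[match(shared, e001$lat_mid)] >=
                    e05$upper[match(shared, e05$lat_mid)]))
  expect_true(all(e001$lower[match(shared, e001$lat_mid)] <=
                    e05$lower[match(shared, e05$lat_mid)]))
  # degenerate single-step set: zero-width envelopes within each band
  degen <- simulate_endpoints(tibble::tibble(dlon = -1, dlat = -2),
                              k_min = 1, k_max = 3, tracks_per_k = 30, seed = 4)
  denv <- null_contours(degen, lat_bin_deg = 1)
  expect_true(all(abs(denv$upper - denv$lower) < 1e-12))
  # sparse bins are flagged unreliable
  sparse <- simulate_endpoints(tibble::tibble(dlon = -1, dlat = -2),
                               k_min = 1, k_max = 3, tracks_per_k = 10, seed = 4)
  expect_true(all(!null_contours(sparse, lat_bin_deg = 1)$reliable))
})

test_that("the endpoint-cloud plot builds without error", {
  cloud <- simulate_endpoints(tibble::tibble(dlon = rnorm(20), dlat = rnorm(20, -2)),
                              k_min = 1, k_max = 3, tracks_per_k = 100, seed = 8)
  p <- plot_endpoint_cloud(cloud,
                           observed = tibble::tibble(dlon = c(-3, 0), dlat = c(-4, -2),
                                                     group = c("displaced", "control")),
                           subsample = 150)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
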