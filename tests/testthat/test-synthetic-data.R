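test_that("track generation is deterministic under a fixed seed", {
  r <- release_sites()$rybachy
  a <- gen_track("b1", r, seed = 5)
  b <- gen_track("b1", r, seed = 5)
  expect_identical(a$track$positions, b$track$positions)
  expect_identical(a$truth, b$truth)
  c <- gen_track("b1", r, seed = 6)
  expect_false(identical(a$track$positions, c$track$positions))
})

test_that("a tightly concentrated due-south compass bird stays on its meridian", {
  r <- release_sites()$rybachy
  params <- strategy_params("clock_compass", heading_mu_deg = 180, kappa = 5000,
                            wander_days = c(0, 0))
  noise <- noise_params(class_mix = c("3" = 1), duty_cycle_hours = 58)
  res <- gen_track("south", r, params, noise, seed = 9)
  expect_equal(res$truth$true_dlon, 0, tolerance = 0.75)
  em <- endpoint_metrics(res$track)
  expect_equal(em$lon_displacement_deg, 0, tolerance = 1)
})

test_that("goal navigators travel along the bearing to their goal", {
  r <- release_sites()$kazan
  goal <- destination_point(r, 250, 2500)
  # travel budget (~15 x 150 km) deliberately short of the goal distance, so
  # the track is an inbound geodesic rather than hovering at the goal
  params <- strategy_params("goal_navigation", kappa = 100, goal = goal,
                            step_shape = 2.5, step_scale_km = 60,
                            n_steps = c(15, 15), wander_days = c(0, 0))
  res <- gen_track("nav", r, params, noise_params(class_mix = c("3" = 1)), seed = 12)
  end <- geo_point(res$truth$true_end_lat, res$truth$true_end_lon)
  expect_gt(gc_distance(r, end), 1200) # made real progress
  expect_lt(gc_distance(end, goal), 2500 - 1000) # towards the goal
  expect_equal(initial_bearing(r, end), initial_bearing(r, goal), tolerance = 5)
})

test_that("partial compensation interpolates between the pure strategies", {
  expect_equal(strategy_params("partial", mix_c = 0)$mix_c, 0)
  expect_equal(strategy_params("clock_compass", mix_c = 0.7)$mix_c, 0)
  expect_equal(strategy_params("goal_navigation", mix_c = 0.2)$mix_c, 1)
  r <- release_sites()$kazan
  set.seed(31)
  dlon_of <- function(strategy, mix_c) {
    mean(replicate(12, {
      p <- strategy_params(strategy, mix_c = mix_c, wander_days = c(0, 0),
                          n_steps = c(12, 12))
      gen_track("x", r, p, noise_params(class_mix = c("3" = 1)))$truth$true_dlon
    }))
  }
  cc <- dlon_of("clock_compass", 0)
  half <- dlon_of("partial", 0.5)
  full <- dlon_of("goal_navigation", 1)
  expect_lt(full, half)
  expect_lt(half, cc)
})

test_that("500-km crossing bearings concentrate around the innate heading", {
  set.seed(41)
  r <- release_sites()$rybachy
  params <- strategy_params("clock_compass", kappa = 20, wander_days = c(0, 2))
  bearings <- vapply(1:100, function(i) {
    trk <- gen_track(paste0("b", i), r, params)$track
    trk <- select_duty_cycle_positions(filter_quality(trk))
    ev <- crossing_event(trk, 500)
    if (is.null(ev)) NA_real_ else ev$bearing_deg
  }, numeric(1))
  bearings <- bearings[!is.na(bearings)]
  expect_gt(length(bearings), 80)
  s <- circular_summary(bearings, conf_level = 0.95)
  # circular mean within the sample's own 95% CI of the innate 195 deg
  expect_lt(abs(wrap_lon(s$mu_deg - 195)), s$ci_halfwidth_deg + 1)
})

test_that("observation noise has the configured per-class magnitude", {
  r <- release_sites()$rybachy
  # a nearly stationary bird isolates the noise from the movement
  params <- strategy_params("clock_compass", kappa = 50,
                            step_shape = 2, step_scale_km = 0.005,
                            n_steps = c(15, 15), wander_days = c(0, 0))
  noise <- noise_params(class_mix = c("1" = 1), fixes_per_window = c(3, 3))
  set.seed(51)
  errs <- unlist(lapply(1:20, function(i) {
    trk <- gen_track(paste0("n", i), r, params, noise)$track
    (trk$positions$lat - r$lat) * 111.19493
  }))
  expect_gt(length(errs), 800)
  expect_lt(abs(stats::sd(errs) - 1.5) / 1.5, 0.2) # class-1 sigma = 1.5 km
})

test_that("cohorts mirror the design, with matching truth table and CSV", {
  coh <- gen_cohort(seed = 61)
  expect_length(coh$tracks, 12)
  expect_equal(nrow(coh$truth), 12)
  expect_identical(sort(names(coh$tracks)), sort(coh$truth$bird_id))
  tab <- table(coh$truth$group, coh$truth$strategy)
  expect_equal(unname(tab["control", "clock_compass"]), 4)
  expect_equal(unname(tab["displaced", "clock_compass"]), 6)
  expect_equal(unname(tab["displaced", "goal_navigation"]), 2)
  # displaced birds start ~1,750 km east of the controls
  d <- gc_distance(coh$tracks[["control_juvenile_01"]]$release_site,
                   coh$tracks[["displaced_juvenile_01"]]$release_site)
  expect_equal(d, 1750, tolerance = 0.01)

  dir <- tempfile()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  back <- read_tracks(paths[["tracks"]], quiet = TRUE)
  expect_setequal(names(back), names(coh$tracks))
  expect_equal(vapply(back, n_positions, integer(1))[names(coh$tracks)],
               vapply(coh$tracks, n_positions, integer(1)))
  truth_back <- readr::read_csv(paths[["truth"]], show_col_types = FALSE)
  expect_identical(sort(truth_back$bird_id), sort(coh$truth$bird_id))

  empty <- gen_cohort(design = tibble::tibble(age = character(0), group = character(0),
                                              n = integer(0), strategy = character(0)),
                      seed = 1)
  expect_length(empty$tracks, 0)
  expect_warning(write_cohort(empty, tempfile()), "Empty cohort")
})

test_that("von Mises draws have the requested mean direction and spread", {
  set.seed(71)
  x <- rvonmises(3000, 120, 15)
  s <- circular_summary(x)
  expect_lt(abs(wrap_lon(s$mu_deg - 120)), 2)
  # r should match A(kappa) = 1 - 1/(2 kappa) approximately for kappa = 15
  expect_equal(s$r, 1 - 1 / (2 * 15) - 1 / (8 * 15^2), tolerance = 0.01)
  # tiny kappa behaves like uniform
  u <- rvonmises(2000, 0, 1e-10)
  expect_lt(circular_summary(u)$r, 0.06)
})
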