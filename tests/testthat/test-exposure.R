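test_that("buffer_average matches exact small-case geometry", {
  # disc fully inside one pixel returns that pixel's value
  v <- matrix(as.numeric(1:9), 3, 3)
  r <- ntl_raster(v, pixel_size = 10)
  expect_equal(buffer_average(r, 15, 15, 3), v[2, 2], tolerance = 1e-12)
  # disc centred on a shared vertical edge: equal areas in both pixels
  r2 <- ntl_raster(matrix(c(2, 10), 1, 2), pixel_size = 10)
  expect_equal(buffer_average(r2, 10, 5, 4), 6, tolerance = 1e-12)
  # constant surface: any disc, any placement (including edge overhang)
  rc <- ntl_raster(matrix(5, 4, 4), pixel_size = 10)
  expect_equal(buffer_average(rc, c(20, 1), c(20, 39), 15), c(5, 5),
               tolerance = 1e-12)
})

test_that("buffer_average agrees with the supersampling oracle", {
  r <- toy_raster(60, 60, seed = 13)
  centers <- list(c(300, 300, 45), c(150, 420, 120), c(95, 95, 80))
  for (cc in centers) {
    got <- buffer_average(r, cc[1], cc[2], cc[3])
    want <- supersample_buffer_mean(r, cc[1], cc[2], cc[3])
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("buffer_average excludes nodata and renormalises", {
  v <- matrix(10, 4, 4); v[2, 2] <- NA
  r <- ntl_raster(v, pixel_size = 10)
  # disc overlapping the nodata pixel still averages to 10 (renormalised)
  expect_equal(buffer_average(r, 20, 20, 12), 10, tolerance = 1e-12)
  # all-nodata coverage errors under strict, NA otherwise
  v2 <- matrix(NA_real_, 2, 2); v2[1, 1] <- 1
  r2 <- ntl_raster(v2, pixel_size = 10)
  expect_error(buffer_average(r2, 15, 5, 3), "no valid pixel")
  expect_true(is.na(buffer_average(r2, 15, 5, 3, strict = FALSE)))
  expect_error(buffer_average(r2, 15, 5, -1), "positive")
})

test_that("buffers straddling the raster edge use covered area only", {
  v <- matrix(c(3, 9), 1, 2)
  r <- ntl_raster(v, pixel_size = 10)
  # disc centre on the left edge: only the covered half matters
  expect_equal(buffer_average(r, 0, 5, 4), 3, tolerance = 1e-12)
  expect_equal(buffer_average(r, 20, 5, 4), 9, tolerance = 1e-12)
})

test_that("residence-based estimators wrap the primitives", {
  r <- toy_raster(30, 30, seed = 2)
  expect_equal(rbm_in_situ(r, 155, 155), pixel_at(r, 155, 155))
  expect_equal(rbm_buffer(r, 155, 155, 40), buffer_average(r, 155, 155, 40))
})

test_that("mobility estimators accumulate weighted nighttime exposure", {
  r <- toy_raster(30, 30, seed = 3)
  # half the duration at night at p1, half by day elsewhere
  traj <- tibble::tibble(
    time = as.POSIXct(c(0, 3600, 7200), origin = "1970-01-01", tz = "UTC"),
    x = c(55, 155, 155), y = c(55, 155, 155),
    night = c(TRUE, FALSE, FALSE))
  traj <- add_temporal_weights(traj)
  m <- mom_in_situ(r, traj)
  expect_equal(m$night_fraction, 0.5)
  expect_equal(m$value, 0.5 * pixel_at(r, 55, 55))
  # night_only renormalises over the nighttime duration
  mn <- mom_in_situ(r, traj, mode = "night_only")
  expect_equal(mn$value, pixel_at(r, 55, 55))
  mb <- mom_buffer(r, traj, 30)
  expect_equal(mb$value, 0.5 * buffer_average(r, 55, 55, 30))
})

test_that("a stationary nighttime trajectory reduces to the home estimate", {
  r <- toy_raster(30, 30, seed = 5)
  traj <- stationary_night_traj(155, 155)
  expect_equal(mom_in_situ(r, traj)$value, rbm_in_situ(r, 155, 155))
  expect_equal(mom_buffer(r, traj, 65)$value, rbm_buffer(r, 155, 155, 65))
  expect_equal(mom_in_situ(r, traj)$night_fraction, 1)
})

test_that("gap fixes contribute zero exposure but keep their weight", {
  r <- toy_raster(30, 30, seed = 6)
  traj <- tibble::tibble(
    time = as.POSIXct(c(0, 3600, 7200), origin = "1970-01-01", tz = "UTC"),
    x = c(55, NA, 55), y = c(55, NA, 55), night = TRUE)
  traj <- add_temporal_weights(traj)
  m <- mom_in_situ(r, traj)
  # the gap hour carries weight in D but adds no exposure
  expect_equal(m$value, 0.5 * pixel_at(r, 55, 55))
  expect_equal(m$night_fraction, 1)
})

test_that("mobility estimators demand prepared trajectories", {
  r <- toy_raster(10, 10)
  traj <- tibble::tibble(x = 5, y = 5)
  expect_error(mom_in_situ(r, traj), "add_temporal_weights")
  expect_error(mom_buffer(r, tibble::tibble(x = 5, y = 5, wt = 1), 10),
               "add_night_flags")
})

test_that("an all-daytime trajectory yields zero full-mode exposure", {
  r <- toy_raster(10, 10)
  traj <- tibble::tibble(
    time = as.POSIXct(c(0, 60, 120), origin = "1970-01-01", tz = "UTC"),
    x = 55, y = 55, night = FALSE)
  traj <- add_temporal_weights(traj)
  expect_equal(mom_in_situ(r, traj)$value, 0)
  expect_true(is.na(mom_in_situ(r, traj, mode = "night_only")$value))
})

test_that("exposure_settings describes the ten base settings", {
  s <- exposure_settings()
  expect_equal(nrow(s), 10)
  expect_equal(sum(s$cross_calibrated), 2)
  expect_setequal(s$setting[s$method == "buffer"],
                  c("b065m", "b100m", "b250m", "b300m", "b500m"))
  expect_equal(s$radius[s$setting == "b065m"], 65)
})

make_small_world <- function(seed = 17) {
  withr::with_seed(seed, {
    v <- matrix(runif(650 * 650, 50, 400), 650, 650)
  })
  world <- ntl_raster(v, pixel_size = 10)
  list(r010 = world,
       r130 = degrade_resolution(world, 13),
       r500 = degrade_resolution(world, 50))
}

fake_cal <- function(slope, intercept) {
  structure(list(slope = slope, intercept = intercept, r2 = 1, n = 10,
                 reference = "a", predictor = "b"),
            class = "ntl_calibration")
}

test_that("exposure_matrix evaluates all settings for all participants", {
  rasters <- make_small_world()
  participants <- tibble::tibble(
    participant_id = c("A", "B"), community = c("SSP", "TSW"),
    home_x = c(2000, 4000), home_y = c(2000, 4000))
  trajectories <- list(A = stationary_night_traj(2000, 2000),
                       B = stationary_night_traj(4000, 4000))
  cals <- list(r130 = fake_cal(1.5, 20), r500 = fake_cal(2, 10))
  emat <- exposure_matrix(participants, trajectories, rasters, cals)
  expect_equal(nrow(emat), 2 * 2 * 10)
  expect_setequal(unique(emat$label),
                  as.vector(outer(c("M_", "R_"), exposure_settings()$setting,
                                  paste0)))
  # R rows equal the direct residence-based estimates
  rb <- emat[emat$label == "R_b100m" & emat$participant_id == "A", ]
  expect_equal(rb$value, rbm_buffer(rasters$r010, 2000, 2000, 100))
  ri <- emat[emat$label == "R_r500m" & emat$participant_id == "B", ]
  expect_equal(ri$value, rbm_in_situ(rasters$r500, 4000, 4000))
  # M rows equal the direct mobility estimates
  mi <- emat[emat$label == "M_r130m" & emat$participant_id == "A", ]
  expect_equal(mi$value, mom_in_situ(rasters$r130, trajectories$A)$value)
  # cross-calibrated rows are the affine image of the raw rows
  raw <- emat[emat$setting == "r130m", ]
  cc <- emat[emat$setting == "r130m_CC", ]
  expect_equal(cc$value, 1.5 * raw$value + 20, tolerance = 1e-12)
  raw5 <- emat[emat$setting == "r500m", ]
  cc5 <- emat[emat$setting == "r500m_CC", ]
  expect_equal(cc5$value, 2 * raw5$value + 10, tolerance = 1e-12)
})

test_that("exposure_matrix validates its inputs", {
  rasters <- make_small_world()
  participants <- tibble::tibble(participant_id = "A", community = "SSP",
                                 home_x = 2000, home_y = 2000)
  trajectories <- list(A = stationary_night_traj(2000, 2000))
  expect_error(
    exposure_matrix(participants, trajectories, rasters[c("r010", "r130")]),
    "needs raster")
  expect_error(
    exposure_matrix(participants, trajectories, rasters, calibrations = NULL),
    "cross-calibration")
  cals <- list(r130 = fake_cal(1, 0), r500 = fake_cal(1, 0))
  expect_error(
    exposure_matrix(participants, list(), rasters, cals),
    "no trajectory")
})

test_that("pivot_exposure yields one row per participant", {
  rasters <- make_small_world()
  participants <- tibble::tibble(
    participant_id = c("A", "B"), community = c("SSP", "TSW"),
    home_x = c(2000, 4000), home_y = c(2000, 4000))
  trajectories <- list(A = stationary_night_traj(2000, 2000),
                       B = stationary_night_traj(4000, 4000))
  cals <- list(r130 = fake_cal(1.5, 20), r500 = fake_cal(2, 10))
  emat <- exposure_matrix(participants, trajectories, rasters, cals)
  wide <- pivot_exposure(emat)
  expect_equal(nrow(wide), 2)
  expect_true(all(c("M_b065m", "R_r500m_CC") %in% names(wide)))
  expect_equal(wide$M_b065m[wide$participant_id == "A"],
               emat$value[emat$label == "M_b065m" &
                            emat$participant_id == "A"])
})
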