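test_that("archetypes carry the documented defaults and validate", {
  old <- community_archetype("old_town")
  expect_equal(old$target_mean, 325.32)
  new <- community_archetype("new_town")
  expect_equal(new$target_mean, 210.78)
  expect_error(community_archetype("old_town", bright_level = 10,
                                   dark_level = 20), "bright_level")
})

test_that("make_nightscape hits its target mean exactly and is seeded", {
  a <- community_archetype("old_town")
  r1 <- make_nightscape(a, width = 130, height = 130, seed = 3)
  expect_equal(mean(r1), 325.32, tolerance = 1e-9)
  expect_true(all(r1$values >= 0))
  r2 <- make_nightscape(a, width = 130, height = 130, seed = 3)
  expect_identical(r1$values, r2$values)
  r3 <- make_nightscape(a, width = 130, height = 130, seed = 4)
  expect_false(identical(r1$values, r3$values))
  expect_error(make_nightscape(a, width = 10, height = 10), "32x32")
})

test_that("residential mask marks the unlit fabric", {
  a <- community_archetype("old_town")
  r <- make_nightscape(a, width = 130, height = 130, seed = 3)
  mask <- attr(r, "residential")
  expect_identical(dim(mask), dim(r$values))
  expect_true(any(mask) && any(!mask))
  # lit fabric (streets) is brighter on average than residential blocks
  expect_gt(mean(r$values[!mask]), mean(r$values[mask]))
  rn <- make_nightscape(community_archetype("new_town"),
                        width = 130, height = 130, seed = 5)
  maskn <- attr(rn, "residential")
  expect_gt(mean(rn$values[!maskn]), mean(rn$values[maskn]))
})

test_that("make_multisensor applies invertible affine distortions", {
  # bright surface so the zero clamp never bites; noiseless distortion
  withr::with_seed(21, {
    v <- matrix(runif(650 * 650, 100, 400), 650, 650)
  })
  truth <- ntl_raster(v, pixel_size = 10)
  sens <- make_multisensor(
    truth,
    distortions = list(r130 = list(slope = 1.47, intercept = 23.14,
                                   noise_sd = 0),
                       r500 = list(slope = 2.20, intercept = 11.71,
                                   noise_sd = 0)))
  expect_identical(sens$r010, truth)
  expect_identical(dim(sens$r130$values), c(50L, 50L))
  expect_identical(dim(sens$r500$values), c(13L, 13L))
  d13 <- degrade_resolution(truth, 13)
  expect_equal(1.47 * sens$r130$values + 23.14, d13$values,
               tolerance = 1e-9)
  d50 <- degrade_resolution(truth, 50)
  expect_equal(2.20 * sens$r500$values + 11.71, d50$values,
               tolerance = 1e-9)
})

test_that("sensor noise is seeded and never produces negatives", {
  withr::with_seed(22, {
    v <- matrix(runif(130 * 130, 0, 60), 130, 130)
  })
  truth <- ntl_raster(v, pixel_size = 10)
  s1 <- make_multisensor(truth, seed = 7, pad = "nodata")
  s2 <- make_multisensor(truth, seed = 7, pad = "nodata")
  expect_identical(s1$r130$values, s2$r130$values)
  expect_true(all(s1$r130$values >= 0, na.rm = TRUE))
  expect_true(all(s1$r500$values >= 0, na.rm = TRUE))
})

test_that("make_trajectory produces a valid prepared trajectory", {
  w <- night_windows("2021-03-22", 3)
  start <- as.POSIXct("2021-03-22 00:00:00", tz = "UTC") - 8 * 3600
  pr <- trajectory_profile(home = c(3000, 3000), days = 2)
  tr <- make_trajectory(pr, w, start, seed = 5)
  expect_equal(nrow(tr), 2 * 1440 + 1)
  expect_true(all(diff(as.numeric(tr$time)) == 60))
  expect_equal(sum(tr$wt), 1, tolerance = 1e-9)
  expect_equal(tr$wt[nrow(tr)], 0)
  expect_true(any(tr$night) && any(!tr$night))
  # most nighttime fixes are at home; excursions leave home
  at_home <- tr$x == 3000 & tr$y == 3000
  expect_gt(mean(at_home[tr$night]), 0.5)
  # reproducible
  tr2 <- make_trajectory(pr, w, start, seed = 5)
  expect_identical(tr, tr2)
  expect_error(trajectory_profile(home = c(0, 0), excursion_radius = -1),
               "nonnegative")
})

test_that("trajectory bounds clamp every position", {
  w <- night_windows("2021-03-22", 2)
  start <- as.POSIXct("2021-03-22 00:00:00", tz = "UTC") - 8 * 3600
  pr <- trajectory_profile(home = c(100, 100), days = 1, day_radius = 5000)
  bounds <- c(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000)
  tr <- make_trajectory(pr, w, start, seed = 9, bounds = bounds)
  expect_true(all(tr$x > 0 & tr$x < 1000))
  expect_true(all(tr$y > 0 & tr$y < 1000))
})

test_that("default demographic marginals are proper distributions", {
  dg <- default_demographics()
  expect_setequal(names(dg), c("SSP", "TSW"))
  for (cm in dg) {
    for (pr in cm) expect_equal(sum(pr), 1, tolerance = 0.01)
  }
  expect_equal(unname(dg$SSP$gender["female"]), 0.577)
})

test_that("make_population places homes on the residential mask", {
  a <- community_archetype("old_town")
  r <- make_nightscape(a, width = 200, height = 200, seed = 3)
  comm <- list(SSP = list(raster = r, mask = attr(r, "residential")),
               TSW = list(raster = r, mask = attr(r, "residential")))
  pop <- make_population(10, comm, seed = 4, margin = 300)
  expect_equal(nrow(pop), 20)
  expect_false(anyDuplicated(pop$participant_id) > 0)
  expect_setequal(unique(pop$community), c("SSP", "TSW"))
  ext <- raster_extent(r)
  expect_true(all(pop$home_x > ext["xmin"] + 290 &
                    pop$home_x < ext["xmax"] - 290))
  # homes sit on residential (unlit-fabric) pixels
  mask <- attr(r, "residential")
  p <- r$pixel_size
  col <- floor((pop$home_x - r$origin_x) / p) + 1
  row <- floor((r$origin_y - pop$home_y) / p) + 1
  expect_true(all(mask[cbind(row, col)]))
  expect_true(all(pop$gender %in% c("male", "female")))
  bad <- default_demographics()
  bad$SSP$gender <- c(male = 0.3, female = 0.3)
  expect_error(make_population(5, comm, demographics = bad), "sum to")
})

test_that("make_outcomes draws consistent seeded outcomes", {
  pop <- tibble::tibble(participant_id = sprintf("P%03d", 1:500))
  e <- seq(100, 500, length.out = 500)
  out <- make_outcomes(pop, setNames(e, pop$participant_id),
                       outcome_model(beta = 0.8), seed = 3)
  expect_equal(nrow(out), 500)
  expect_identical(out$healthy, out$health_score <= 3)
  expect_true(all(out$health_score %in% 1:6))
  out2 <- make_outcomes(pop, e, outcome_model(beta = 0.8), seed = 3)
  expect_identical(out, out2)
  # beta = 0: healthy share near plogis(intercept)
  out0 <- make_outcomes(pop, e, outcome_model(beta = 0), seed = 4)
  expect_equal(mean(out0$healthy), 0.875, tolerance = 0.05)
  # strong positive beta: the healthy are more exposed on average
  expect_gt(mean(e[out$healthy]), mean(e[!out$healthy]))
  expect_error(make_outcomes(pop, c(e[-1], NA)), "finite")
})

test_that("simulate_study wires the whole generator together", {
  st <- simulate_study(seed = 2, n_per_community = 2, days = 1,
                       n_cal_pairs = 25)
  expect_setequal(names(st$rasters), c("r010", "r130", "r500"))
  expect_identical(dim(st$rasters$r010$values), c(650L, 1300L))
  expect_identical(dim(st$rasters$r500$values), c(13L, 26L))
  expect_equal(nrow(st$participants), 4)
  expect_setequal(names(st$trajectories), st$participants$participant_id)
  tr <- st$trajectories[[1]]
  expect_true(all(c("x", "y", "night", "wt") %in% names(tr)))
  expect_equal(sum(tr$wt), 1, tolerance = 1e-9)
  expect_s3_class(st$calibrations$r130, "ntl_calibration")
  expect_equal(st$calibrations$r130$n, 25)
  # SSP homes on the left (old town) tile, TSW on the right
  expect_true(all(st$participants$home_x[st$participants$community ==
                                           "SSP"] < 6500))
  expect_true(all(st$participants$home_x[st$participants$community ==
                                           "TSW"] > 6500))
  expect_equal(st$params$seed, 2)
})
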