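#' Community nightscape archetypes
#'
#' Parameter bundles describing the two contrasting community nightscapes
#' the generator emulates: a dense **old town** whose low blocks are
#' enclosed by bright street grids, and a more open **new town** with
#' sparse bright patches on a darker matrix surrounded by rural settings.
#' Default target mean luminosities are the two communities' observed
#' averages on the calibrated 10 m product (325.32 and 210.78
#' nW cm^-2 sr^-1).
#'
#' @param name `"old_town"` or `"new_town"`.
#' @param target_mean Raster mean luminosity to realise, nW cm^-2 sr^-1.
#' @param street_spacing Street-grid (old town) or bright-patch (new town)
#'   spacing, metres.
#' @param bright_level,dark_level Pre-texture luminosity of lit/unlit
#'   fabric, nW cm^-2 sr^-1 (`bright_level > dark_level >= 0`).
#' @param heterogeneity Target coefficient of variation of the
#'   multiplicative lognormal texture.
#' @return A `community_archetype` list.
#' @export
community_archetype <- function(name = c("old_town", "new_town"),
                                target_mean = NULL, street_spacing = NULL,
                                bright_level = NULL, dark_level = NULL,
                                heterogeneity = NULL) {
  name <- match.arg(name)
  def <- if (name == "old_town") {
    list(target_mean = 325.32, street_spacing = 60, bright_level = 700,
         dark_level = 150, heterogeneity = 0.35)
  } else {
    list(target_mean = 210.78, street_spacing = 250, bright_level = 550,
         dark_level = 100, heterogeneity = 0.45)
  }
  out <- list(name = name,
              target_mean = target_mean %||% def$target_mean,
              street_spacing = street_spacing %||% def$street_spacing,
              bright_level = bright_level %||% def$bright_level,
              dark_level = dark_level %||% def$dark_level,
              heterogeneity = heterogeneity %||% def$heterogeneity)
  if (out$bright_level <= out$dark_level || out$dark_level < 0) {
    abort("need bright_level > dark_level >= 0.")
  }
  structure(out, class = "community_archetype")
}

#' Generate a synthetic community nightscape
#'
#' Builds a seeded 10 m luminosity grid for one community archetype:
#' a bright street grid on dark blocks (old town) or sparse bright patches
#' on a darker matrix (new town), overlaid with multiplicative lognormal
#' texture (strictly positive and right-skewed, like city radiance) and
#' rescaled so the raster mean matches the archetype's target exactly.
#' The returned raster carries a logical `residential` attribute marking
#' unlit-fabric pixels (block interiors / patch surroundings) where homes
#' are placed, which is what makes residence-based and mobility-oriented
#' exposures genuinely differ.
#'
#' @param archetype A [community_archetype()].
#' @param width,height Grid size in pixels (>= 32).
#' @param pixel_size Pixel edge, metres (default 10).
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param origin_x,origin_y Placement of the upper-left corner, metres.
#' @return An [ntl_raster] with attribute `residential`.
#' @export
make_nightscape <- function(archetype, width = 650, height = 650,
                            pixel_size = 10, seed = 1,
                            origin_x = 0, origin_y = height * pixel_size) {
  stopifnot(inherits(archetype, "community_archetype"))
  if (width < 32 || height < 32) abort("nightscape must be at least 32x32.")
  a <- archetype
  withr::with_seed(seed, {
    base <- matrix(a$dark_level, height, width)
    if (a$name == "old_town") {
      sp <- max(2L, round(a$street_spacing / pixel_size))
      street_rows <- seq(sp, height, by = sp)
      street_cols <- seq(sp, width, by = sp)
      base[street_rows, ] <- a$bright_level
      base[, street_cols] <- a$bright_level
      residential <- matrix(TRUE, height, width)
      residential[street_rows, ] <- FALSE
      residential[, street_cols] <- FALSE
    } else {
      sp <- max(4L, round(a$street_spacing / pixel_size))
      patch_r <- max(2L, round(sp / 4))
      centers_i <- seq(sp %/% 2, height, by = sp)
      centers_j <- seq(sp %/% 2, width, by = sp)
      lit <- matrix(FALSE, height, width)
      for (ci in centers_i) {
        for (cj in centers_j) {
          pi <- ci + sample.int(5, 1) - 3L
          pj <- cj + sample.int(5, 1) - 3L
          ii <- pmax(1L, pi - patch_r):pmin(height, pi + patch_r)
          jj <- pmax(1L, pj - patch_r):pmin(width, pj + patch_r)
          d2 <- outer((ii - pi)^2, (jj - pj)^2, `+`)
          lit[ii, jj][d2 <= patch_r^2] <- TRUE
        }
      }
      base[lit] <- a$bright_level
      residential <- !lit
    }
    sdlog <- sqrt(log(1 + a$heterogeneity^2))
    texture <- matrix(rlnorm(height * width, -sdlog^2 / 2, sdlog),
                      height, width)
    # km-scale urban-core-to-periphery luminosity falloff: city radiance is
    # non-stationary, brightest around a core and fading to the rural fringe
    core_i <- runif(1, 0.3, 0.7) * height
    core_j <- runif(1, 0.3, 0.7) * width
    sigma <- 0.35 * max(height, width)
    d2 <- outer((seq_len(height) - core_i)^2, (seq_len(width) - core_j)^2,
                `+`)
    gradient <- 0.35 + 1.35 * exp(-d2 / (2 * sigma^2))
    v <- base * texture * gradient
  })
  m <- mean(v)
  if (m <= 0) abort("unattainable target mean: generated surface is dark.")
  v <- v * (a$target_mean / m)
  out <- ntl_raster(v, origin_x, origin_y, pixel_size,
                    crs = "synthetic-planar", units = "band_radiance")
  attr(out, "residential") <- residential
  out
}

#' Emulate multi-resolution multi-sensor views of one nightscape
#'
#' Treats the 10 m raster as ground truth and derives a 130 m and a 500 m
#' sensor view by block-average degradation (factors 13 and 50) followed by
#' an affine radiometric distortion with pixel noise,
#' `sensor = (truth - intercept) / slope + noise`, so that regressing
#' fine-product buffer means back on the sensor's buffer means recovers
#' `slope` and `intercept` as the cross-calibration ground truth. Negative
#' distorted radiances are clipped at zero. Default distortions echo the
#' fitted cross-calibration models of the three-sensor study
#' (slope 1.47 / intercept 23.14 for 130 m, 2.20 / 11.71 for 500 m).
#'
#' @param truth A 10 m [ntl_raster] whose dimensions are divisible by 13
#'   and 50 (or set `pad = "nodata"`).
#' @param distortions Named list (`r130`, `r500`) of lists with `slope`,
#'   `intercept`, `noise_sd`.
#' @param seed Integer seed for the distortion noise.
#' @param pad Passed to [degrade_resolution()].
#' @return List `r010` (the truth), `r130`, `r500` ([ntl_raster]s) and
#'   `distortions` (the recorded ground truth).
#' @export
make_multisensor <- function(truth,
                             distortions = list(
                               r130 = list(slope = 1.47, intercept = 23.14,
                                           noise_sd = 2),
                               r500 = list(slope = 2.20, intercept = 11.71,
                                           noise_sd = 2)),
                             seed = 1, pad = "error") {
  stopifnot(inherits(truth, "ntl_raster"))
  distort <- function(ras, d, sub_seed) {
    withr::with_seed(sub_seed, {
      v <- (ras$values - d$intercept) / d$slope
      if (d$noise_sd > 0) v <- v + rnorm(length(v), 0, d$noise_sd)
    })
    ras$values <- pmax(v, 0)
    ras
  }
  mid <- distort(degrade_resolution(truth, 13, pad = pad),
                 distortions$r130, seed + 1L)
  coarse <- distort(degrade_resolution(truth, 50, pad = pad),
                    distortions$r500, seed + 2L)
  list(r010 = truth, r130 = mid, r500 = coarse, distortions = distortions)
}

#' Trajectory generation profile
#'
#' @param home Length-2 numeric home coordinates `c(x, y)`, metres.
#' @param days Survey length in days (default 7: 5 weekdays + 2 weekend
#'   days).
#' @param excursions_per_night Poisson rate of nighttime outings.
#' @param excursion_radius Maximum outing distance from home, metres.
#' @param excursion_duration Mean outing duration, minutes.
#' @param day_radius Scale of daytime wandering around home, metres.
#' @param interval Fix spacing, seconds (default 60).
#' @return A `trajectory_profile` list.
#' @export
trajectory_profile <- function(home, days = 7, excursions_per_night = 1,
                               excursion_radius = 400,
                               excursion_duration = 45, day_radius = 1500,
                               interval = 60) {
  if (excursions_per_night < 0 || excursion_radius < 0) {
    abort("rates and radii must be nonnegative.")
  }
  structure(list(home = home, days = days,
                 excursions_per_night = excursions_per_night,
                 excursion_radius = excursion_radius,
                 excursion_duration = excursion_duration,
                 day_radius = day_radius, interval = interval),
            class = "trajectory_profile")
}

#' Generate a home-anchored 7-day 1-minute trajectory
#'
#' Simulates a week of regular fixes: by day the participant wanders in a
#' wide neighbourhood around home (a mean-reverting walk; daytime positions
#' never contribute exposure, which is zero by definition before sunset);
#' by night the participant is at home except for Poisson-seeded outings of
#' lognormal duration that walk out to a random target within
#' `excursion_radius` and back, with small GPS-scale jitter. Positions are
#' clamped to `bounds`. Timestamps are strictly increasing; `night` flags
#' and temporal weights are attached.
#'
#' @param profile A [trajectory_profile()].
#' @param windows Night windows from [night_windows()] covering the span.
#' @param start Local-midnight `POSIXct` start of day 1 (UTC-based).
#' @param seed Integer seed.
#' @param bounds Optional extent (as [raster_extent()]) to clamp positions.
#' @return Trajectory tibble with `time`, `x`, `y`, `night`, `wt`.
#' @export
make_trajectory <- function(profile, windows, start, seed = 1,
                            bounds = NULL) {
  stopifnot(inherits(profile, "trajectory_profile"))
  pr <- profile
  n <- pr$days * 86400 %/% pr$interval + 1
  tt <- as.numeric(start) + (seq_len(n) - 1) * pr$interval
  withr::with_seed(seed, {
    # nighttime flag from the supplied windows
    night <- rep(FALSE, n)
    for (k in seq_len(nrow(windows))) {
      if (windows$polar[k] == "always_night") {
        d0 <- as.numeric(as.POSIXct(windows$date[k], tz = "UTC"))
        night[tt >= d0 & tt < d0 + 86400] <- TRUE
      } else if (windows$polar[k] == "normal") {
        night[tt > as.numeric(windows$sunset[k]) &
                tt < as.numeric(windows$sunrise_next[k])] <- TRUE
      }
    }
    # daytime: mean-reverting wander around home
    phi <- 0.995
    sd_step <- pr$day_radius * sqrt(1 - phi^2) / 1.5
    zx <- stats::filter(rnorm(n, 0, sd_step), phi, "recursive")
    zy <- stats::filter(rnorm(n, 0, sd_step), phi, "recursive")
    x <- pr$home[1] + as.numeric(zx)
    y <- pr$home[2] + as.numeric(zy)
    # nighttime: at home, with occasional out-and-back excursions
    x[night] <- pr$home[1]
    y[night] <- pr$home[2]
    for (k in seq_len(nrow(windows))) {
      if (windows$polar[k] == "always_day") next
      w0 <- if (windows$polar[k] == "always_night")
        as.numeric(as.POSIXct(windows$date[k], tz = "UTC")) else
          as.numeric(windows$sunset[k])
      w1 <- if (windows$polar[k] == "always_night") w0 + 86400 else
        as.numeric(windows$sunrise_next[k])
      n_exc <- rpois(1, pr$excursions_per_night)
      for (e in seq_len(n_exc)) {
        dur <- 60 * min(120, max(10, rlnorm(1, log(pr$excursion_duration),
                                            0.4)))
        t0 <- runif(1, w0, max(w0, w1 - dur))
        theta <- runif(1, 0, 2 * pi)
        dist <- runif(1, 50, max(51, pr$excursion_radius))
        idx <- which(tt >= t0 & tt <= t0 + dur & night)
        if (!length(idx)) next
        u <- (tt[idx] - t0) / dur
        reach <- 1 - abs(2 * u - 1)          # walk out, then back
        x[idx] <- pr$home[1] + dist * cos(theta) * reach +
          rnorm(length(idx), 0, 8)
        y[idx] <- pr$home[2] + dist * sin(theta) * reach +
          rnorm(length(idx), 0, 8)
      }
    }
  })
  if (!is.null(bounds)) {
    eps <- 1e-6
    x <- pmin(pmax(x, bounds["xmin"] + eps), bounds["xmax"] - eps)
    y <- pmin(pmax(y, bounds["ymin"] + eps), bounds["ymax"] - eps)
  }
  traj <- tibble::tibble(
    time = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
    x = x, y = y, night = night)
  add_temporal_weights(traj)
}

#' Default socio-demographic marginals for the two communities
#'
#' Category proportions matching the surveyed cohort's profiles (e.g.
#' 57.7% female in the old-town community).
#'
#' @return Named list (one element per community) of named probability
#'   vectors.
#' @export
default_demographics <- function() {
  list(
    SSP = list(
      gender = c(male = 0.423, female = 0.577),
      age_group = c("18-24" = 0.154, "25-44" = 0.500, "45-64" = 0.346),
      income_group = c(low = 0.452, middle = 0.308, high = 0.240),
      education_group = c(low = 0.356, middle = 0.529, high = 0.115),
      marital_group = c(single = 0.510, married = 0.385, other = 0.105)),
    TSW = list(
      gender = c(male = 0.462, female = 0.538),
      age_group = c("18-24" = 0.202, "25-44" = 0.490, "45-64" = 0.308),
      income_group = c(low = 0.260, middle = 0.462, high = 0.278),
      education_group = c(low = 0.346, middle = 0.538, high = 0.116),
      marital_group = c(single = 0.558, married = 0.337, other = 0.105))
  )
}

#' Generate a synthetic cohort
#'
#' Draws socio-demographic categories from the configured marginal
#' proportions and places each home uniformly at random on the community's
#' residential mask (unlit-fabric pixels), jittered within the pixel.
#'
#' @param n_per_community Participants per community.
#' @param communities Named list; each element has `raster` (an
#'   [ntl_raster]) and `mask` (logical matrix of allowed home pixels).
#' @param demographics Marginal proportions as [default_demographics()];
#'   each vector must sum to 1 (tolerance 0.01).
#' @param seed Integer seed.
#' @param margin Homes are kept at least this far (metres) from the raster
#'   edge so home buffers are fully covered.
#' @return Tibble: `participant_id`, `community`, `home_x`, `home_y` and
#'   the categorical covariates.
#' @export
make_population <- function(n_per_community = 104, communities,
                            demographics = default_demographics(),
                            seed = 1, margin = 520) {
  if (n_per_community < 1) abort("`n_per_community` must be >= 1.")
  for (cm in names(demographics)) {
    for (vn in names(demographics[[cm]])) {
      pr <- demographics[[cm]][[vn]]
      if (abs(sum(pr) - 1) > 0.01) {
        abort(sprintf("proportions for %s/%s sum to %.3f, not 1.",
                      cm, vn, sum(pr)))
      }
    }
  }
  stopifnot(all(names(demographics) %in% names(communities)))
  withr::with_seed(seed, {
    rows <- purrr::map(names(demographics), function(cm) {
      ras <- communities[[cm]]$raster
      mask <- communities[[cm]]$mask
      p <- ras$pixel_size
      ext <- raster_extent(ras)
      nr <- nrow(ras$values); nc <- ncol(ras$values)
      cand <- which(mask)
      ri <- (cand - 1) %% nr + 1
      cj <- (cand - 1) %/% nr + 1
      cx <- ras$origin_x + (cj - 0.5) * p
      cy <- ras$origin_y - (ri - 0.5) * p
      ok <- cx > ext["xmin"] + margin & cx < ext["xmax"] - margin &
        cy > ext["ymin"] + margin & cy < ext["ymax"] - margin
      if (!any(ok)) abort("no residential pixels left after edge margin.")
      pick <- sample(which(ok), n_per_community, replace = TRUE)
      out <- tibble::tibble(
        participant_id = sprintf("%s_%03d", cm, seq_len(n_per_community)),
        community = cm,
        home_x = cx[pick] + runif(n_per_community, -p / 2, p / 2),
        home_y = cy[pick] + runif(n_per_community, -p / 2, p / 2))
      for (vn in names(demographics[[cm]])) {
        pr <- demographics[[cm]][[vn]]
        out[[vn]] <- sample(names(pr), n_per_community, replace = TRUE,
                            prob = pr)
      }
      out
    }) |> purrr::list_rbind()
  })
  rows
}

#' Outcome-generation model
#'
#' @param beta Log-odds of being healthy per `scale` units of exposure.
#' @param intercept Log-odds at the centring exposure; the default
#'   `qlogis(0.875)` anchors the healthy share near the cohort's observed
#'   87.5%.
#' @param scale Exposure units per coefficient unit (default 100).
#' @param center Exposure value at which the intercept applies; `NULL`
#'   centres at the cohort mean.
#' @param covariate_effects Optional named list of named numeric vectors of
#'   extra log-odds per covariate category.
#' @return An `outcome_model` list.
#' @export
outcome_model <- function(beta = 0.8, intercept = qlogis(0.875),
                          scale = 100, center = NULL,
                          covariate_effects = NULL) {
  structure(list(beta = beta, intercept = intercept, scale = scale,
                 center = center, covariate_effects = covariate_effects),
            class = "outcome_model")
}

#' Generate binary health outcomes from true exposures
#'
#' Draws `healthy ~ Bernoulli(plogis(intercept + beta * (e - center)/scale
#' + covariate terms))` and back-fills a 6-point self-rated health score
#' consistent with the binary draw (1-3 for healthy, 4-6 otherwise).
#'
#' @param participants Cohort tibble from [make_population()].
#' @param true_exposure Numeric vector of exposures, named by
#'   `participant_id` (or in `participants` order).
#' @param model An [outcome_model()].
#' @param seed Integer seed.
#' @return Tibble: `participant_id`, `healthy`, `health_score`.
#' @export
make_outcomes <- function(participants, true_exposure,
                          model = outcome_model(), seed = 1) {
  e <- if (!is.null(names(true_exposure))) {
    unname(true_exposure[participants$participant_id])
  } else rep_len(true_exposure, nrow(participants))
  if (anyNA(e) || any(!is.finite(e))) abort("exposures must be finite.")
  center <- model$center %||% mean(e)
  lp <- model$intercept + model$beta * (e - center) / model$scale
  if (!is.null(model$covariate_effects)) {
    for (vn in names(model$covariate_effects)) {
      eff <- model$covariate_effects[[vn]]
      lp <- lp + dplyr::coalesce(eff[participants[[vn]]], 0)
    }
  }
  withr::with_seed(seed, {
    healthy <- rbinom(length(lp), 1, plogis(lp)) == 1
    score <- integer(length(lp))
    score[healthy] <- sample(1:3, sum(healthy), replace = TRUE,
                             prob = c(0.2, 0.4, 0.4))
    score[!healthy] <- sample(4:6, sum(!healthy), replace = TRUE,
                              prob = c(0.5, 0.35, 0.15))
  })
  tibble::tibble(participant_id = participants$participant_id,
                 healthy = healthy, health_score = score)
}

#' Simulate a complete two-community study
#'
#' End-to-end seeded generator for the whole measurement framework: builds
#' the two community nightscapes side by side on one 10 m world grid,
#' derives the 130 m and 500 m sensor views with known affine distortions,
#' fits the cross-sensor calibrations from randomly placed 1 km buffer
#' pairs, draws the cohort with community-matched demographics, and
#' simulates a week of 1-minute trajectories per participant with
#' nighttime flags and temporal weights attached. Everything is a pure
#' function of (parameters, seed).
#'
#' @param seed Master integer seed.
#' @param n_per_community Participants per community (default 104).
#' @param days Survey days (default 7).
#' @param start_date First local survey date.
#' @param tile_px Width/height of each community tile in 10 m pixels
#'   (default 650, i.e. 6.5 km; divisible by both degradation factors).
#' @param anchor `c(lon, lat)` of the synthetic city (default Hong Kong);
#'   the planar grid is local, solar events use this anchor.
#' @param tz_offset Local clock offset, hours east of UTC.
#' @param n_cal_pairs,cal_radius Cross-calibration sampling design
#'   (defaults 294 pairs, 1000 m buffers).
#' @param archetypes List with `old` and `new` [community_archetype()]s.
#' @param distortions Passed to [make_multisensor()].
#' @param profile_args Named list of overrides for [trajectory_profile()].
#' @return List with `rasters` (`r010`, `r130`, `r500`), `calibrations`
#'   (`r130`, `r500`), `participants`, `trajectories` (named list),
#'   `windows`, `communities` (masks + geometry) and `params`.
#' @export
simulate_study <- function(seed = 1, n_per_community = 104, days = 7,
                           start_date = "2021-03-22", tile_px = 650,
                           anchor = c(114.1, 22.3), tz_offset = 8,
                           n_cal_pairs = 294, cal_radius = 1000,
                           archetypes = list(
                             old = community_archetype("old_town"),
                             new = community_archetype("new_town")),
                           distortions = NULL, profile_args = list()) {
  pixel <- 10
  ns_old <- make_nightscape(archetypes$old, tile_px, tile_px, pixel,
                            seed = seed + 1L)
  ns_new <- make_nightscape(archetypes$new, tile_px, tile_px, pixel,
                            seed = seed + 2L)
  world_vals <- cbind(ns_old$values, ns_new$values)
  world <- ntl_raster(world_vals, 0, tile_px * pixel, pixel,
                      crs = "synthetic-planar", units = "band_radiance")
  pad_mask <- function(m, side) {
    full <- matrix(FALSE, tile_px, 2 * tile_px)
    cols <- if (side == "left") seq_len(tile_px) else
      tile_px + seq_len(tile_px)
    full[, cols] <- m
    full
  }
  communities <- list(
    SSP = list(raster = world,
               mask = pad_mask(attr(ns_old, "residential"), "left")),
    TSW = list(raster = world,
               mask = pad_mask(attr(ns_new, "residential"), "right")))

  sensors <- if (is.null(distortions)) {
    make_multisensor(world, seed = seed + 3L)
  } else {
    make_multisensor(world, distortions = distortions, seed = seed + 3L)
  }

  pairs130 <- sample_buffer_pairs(sensors$r010, sensors$r130,
                                  n = n_cal_pairs, radius = cal_radius,
                                  seed = seed + 4L)
  pairs500 <- sample_buffer_pairs(sensors$r010, sensors$r500,
                                  n = n_cal_pairs, radius = cal_radius,
                                  seed = seed + 5L)
  calibrations <- list(
    r130 = fit_cross_calibration(pairs130, "glimmer-10m", "pan-130m"),
    r500 = fit_cross_calibration(pairs500, "glimmer-10m", "dnb-500m"))

  participants <- make_population(n_per_community, communities,
                                  seed = seed + 6L)

  windows <- night_windows(start_date, days + 1, anchor[1], anchor[2],
                           tz_offset)
  start <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC") -
    tz_offset * 3600
  bounds <- raster_extent(world)
  trajectories <- purrr::map(seq_len(nrow(participants)), function(k) {
    pr <- do.call(trajectory_profile, c(
      list(home = c(participants$home_x[k], participants$home_y[k]),
           days = days), profile_args))
    make_trajectory(pr, windows, start, seed = seed + 1000L + k,
                    bounds = bounds)
  })
  names(trajectories) <- participants$participant_id

  list(rasters = sensors[c("r010", "r130", "r500")],
       calibrations = calibrations, participants = participants,
       trajectories = trajectories, windows = windows,
       communities = communities,
       params = list(seed = seed, n_per_community = n_per_community,
                     days = days, start_date = start_date,
                     tile_px = tile_px, anchor = anchor,
                     tz_offset = tz_offset,
                     distortions = sensors$distortions,
                     n_cal_pairs = n_cal_pairs, cal_radius = cal_radius))
}
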