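#' Sunrise and sunset times (NOAA solar position algorithm)
#'
#' Computes apparent sunrise and sunset (sun-centre altitude -0.833 degrees,
#' atmospheric refraction included) for each calendar date at the given
#' longitude/latitude, following the NOAA solar calculator equations. The
#' night window for date `d` runs from `sunset` on `d` to `sunrise_next` on
#' `d + 1`. All returned times are absolute `POSIXct` in UTC; `tz_offset`
#' only selects which local calendar day each date label refers to.
#'
#' At high latitudes the sun may not cross the horizon; such days are
#' reported with `polar = "always_day"` or `"always_night"` and `NA` event
#' times.
#'
#' @param date `Date` vector (local calendar dates).
#' @param lon,lat Degrees (east/north positive), `|lat| <= 90`,
#'   `|lon| <= 180`. Recycled against `date`.
#' @param tz_offset Hours east of UTC of the local clock (default +8).
#' @return Tibble with columns `date`, `sunrise`, `sunset`, `sunrise_next`,
#'   `polar` (one of `"normal"`, `"always_day"`, `"always_night"`).
#' @examples
#' solar_events(as.Date("2021-03-22"), lon = 114.1, lat = 22.3)
#' @export
solar_events <- function(date, lon, lat, tz_offset = 8) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    abort("invalid coordinates: need |lat| <= 90 and |lon| <= 180.")
  }
  date <- as.Date(date)
  n <- max(length(date), length(lon), length(lat))
  date <- rep_len(date, n); lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  ev <- solar_day(date, lon, lat, tz_offset)
  ev_next <- solar_day(date + 1, lon, lat, tz_offset)
  tibble::tibble(date = date, sunrise = ev$sunrise, sunset = ev$sunset,
                 sunrise_next = ev_next$sunrise, polar = ev$polar)
}

# Core NOAA computation for one set of dates; evaluated at local solar noon,
# accurate to well under two minutes for civil purposes.
solar_day <- function(date, lon, lat, tz_offset) {
  rad <- pi / 180
  days <- as.numeric(date)                      # days since 1970-01-01 (UTC)
  jd <- days + 2440587.5 + (12 - tz_offset) / 24  # Julian day at local noon
  jc <- (jd - 2451545) / 36525
  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqc <- sin(rad * gma) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(rad * 2 * gma) * (0.019993 - 0.000101 * jc) +
    sin(rad * 3 * gma) * 0.000289
  stl <- gml + eqc
  sal <- stl - 0.00569 - 0.00478 * sin(rad * (125.04 - 1934.136 * jc))
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos(rad * (125.04 - 1934.136 * jc))
  decl <- asin(sin(rad * oc) * sin(rad * sal)) / rad
  vy <- tan(rad * oc / 2)^2
  eqtime <- 4 / rad * (vy * sin(2 * rad * gml) - 2 * ecc * sin(rad * gma) +
    4 * ecc * vy * sin(rad * gma) * cos(2 * rad * gml) -
    0.5 * vy^2 * sin(4 * rad * gml) - 1.25 * ecc^2 * sin(2 * rad * gma))
  cos_ha <- (cos(rad * 90.833) - sin(rad * lat) * sin(rad * decl)) /
    (cos(rad * lat) * cos(rad * decl))
  polar <- rep("normal", length(date))
  polar[cos_ha > 1] <- "always_night"
  polar[cos_ha < -1] <- "always_day"
  ha <- acos(pmin(1, pmax(-1, cos_ha))) / rad
  # minutes from 00:00 UTC of the local calendar date
  rise_min <- 720 - 4 * (lon + ha) - eqtime
  set_min <- 720 - 4 * (lon - ha) - eqtime
  base <- as.POSIXct(days * 86400, origin = "1970-01-01", tz = "UTC")
  sunrise <- base + rise_min * 60
  sunset <- base + set_min * 60
  sunrise[polar != "normal"] <- NA
  sunset[polar != "normal"] <- NA
  list(sunrise = sunrise, sunset = sunset, polar = polar)
}

#' Night windows over a survey span
#'
#' Convenience wrapper building one [solar_events()] row per survey date.
#'
#' @param start_date First local date (`Date` or string).
#' @param n_days Number of consecutive dates.
#' @inheritParams solar_events
#' @export
night_windows <- function(start_date, n_days, lon = 114.1, lat = 22.3,
                          tz_offset = 8) {
  solar_events(as.Date(start_date) + seq_len(n_days) - 1, lon, lat, tz_offset)
}

#' Flag nighttime fixes on a trajectory
#'
#' A fix is nighttime iff its timestamp lies strictly between the local
#' sunset and the following sunrise; timestamps exactly equal to sunset or
#' sunrise count as daytime. By default solar events are evaluated at each
#' fix's own longitude/latitude (columns `lon`, `lat` if present); otherwise
#' a fixed `anchor = c(lon, lat)` reference point is used.
#'
#' @param traj Trajectory tibble with columns `time` (`POSIXct`) and,
#'   optionally, `lon`/`lat`.
#' @param anchor Length-2 numeric `c(lon, lat)` fallback reference.
#' @param tz_offset Hours east of UTC of the local clock.
#' @return `traj` with a logical `night` column added.
#' @export
add_night_flags <- function(traj, anchor = c(114.1, 22.3), tz_offset = 8) {
  stopifnot(is.data.frame(traj), "time" %in% names(traj))
  t <- traj$time
  if (!inherits(t, "POSIXct")) abort("`time` must be POSIXct.")
  local_date <- as.Date(floor((as.numeric(t) + tz_offset * 3600) / 86400),
                        origin = "1970-01-01")
  per_fix <- all(c("lon", "lat") %in% names(traj)) &&
    !anyNA(traj$lon) && !anyNA(traj$lat)
  if (per_fix) {
    key <- paste(local_date, round(traj$lon, 3), round(traj$lat, 3))
    uk <- !duplicated(key)
    ev <- solar_events(local_date[uk], traj$lon[uk], traj$lat[uk], tz_offset)
    idx <- match(key, key[uk])
  } else {
    uk <- !duplicated(local_date)
    ev <- solar_events(local_date[uk], anchor[1], anchor[2], tz_offset)
    idx <- match(local_date, local_date[uk])
  }
  polar <- ev$polar[idx]
  sunrise <- ev$sunrise[idx]
  sunset <- ev$sunset[idx]
  night <- (t > sunset) | (t < sunrise)
  night[polar == "always_night"] <- TRUE
  night[polar == "always_day"] <- FALSE
  traj$night <- night
  traj
}
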