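#' Assemble a regular 1-minute trajectory from raw GPS fixes
#'
#' Sorts raw fixes by time, collapses exact-duplicate timestamps to their
#' mean position, optionally smooths the track with a constant-velocity
#' Kalman filter, and resamples onto a regular `interval`-second grid by
#' linear interpolation of the (smoothed) track. Grid points falling inside
#' a raw-data gap longer than `gap_threshold` seconds are flagged
#' (`gap = TRUE`) and carry `NA` coordinates rather than interpolated
#' positions: long gaps are reported, never silently filled.
#'
#' When the input is already on the regular grid and smoothing is disabled
#' the trajectory is returned unchanged (up to column ordering).
#'
#' @param fixes Tibble with columns `time` (`POSIXct`), `x`, `y` (metres,
#'   planar CRS) and optionally `lon`, `lat`, `participant_id`.
#' @param interval Nominal fix spacing in seconds (default 60).
#' @param smooth Apply the Kalman filter? Default `FALSE` (synthetic tracks
#'   are already noise-free; the exposure estimators are independent of the
#'   smoother).
#' @param process_sd Continuous white-noise acceleration intensity,
#'   m s^-3/2 (Kalman process noise).
#' @param measure_sd GPS measurement noise standard deviation, metres.
#' @param gap_threshold Gap length in seconds above which grid points are
#'   flagged instead of interpolated (default 1800 s = 30 min).
#' @return Tibble with columns `time`, `x`, `y`, `gap` (plus `lon`, `lat`
#'   and `participant_id` when present, interpolated/propagated).
#' @export
assemble_trajectory <- function(fixes, interval = 60, smooth = FALSE,
                                process_sd = 0.5, measure_sd = 10,
                                gap_threshold = 1800) {
  stopifnot(is.data.frame(fixes), all(c("time", "x", "y") %in% names(fixes)))
  f <- dplyr::arrange(tibble::as_tibble(fixes), .data$time)
  if (anyNA(f$time)) abort("fixes contain missing timestamps.")
  # collapse duplicated timestamps to the mean position
  if (anyDuplicated(f$time)) {
    keep <- intersect(c("x", "y", "lon", "lat"), names(f))
    f <- dplyr::summarise(dplyr::group_by(f, .data$time),
                          dplyr::across(dplyr::all_of(keep), mean),
                          .groups = "drop")
  }
  if (nrow(f) < 2) abort("need at least 2 usable fixes.")
  tt <- as.numeric(f$time)
  if (smooth) {
    f$x <- kalman_cv(tt, f$x, process_sd, measure_sd)
    f$y <- kalman_cv(tt, f$y, process_sd, measure_sd)
  }
  grid <- seq(tt[1], tt[length(tt)], by = interval)
  out <- tibble::tibble(
    time = as.POSIXct(grid, origin = "1970-01-01",
                      tz = attr(fixes$time, "tzone") %||% "UTC"),
    x = approx(tt, f$x, xout = grid)$y,
    y = approx(tt, f$y, xout = grid)$y)
  if (all(c("lon", "lat") %in% names(f))) {
    out$lon <- approx(tt, f$lon, xout = grid)$y
    out$lat <- approx(tt, f$lat, xout = grid)$y
  }
  # flag grid points strictly inside long raw gaps
  gaps <- which(diff(tt) > gap_threshold)
  out$gap <- FALSE
  for (g in gaps) {
    inside <- grid > tt[g] & grid < tt[g + 1]
    out$gap[inside] <- TRUE
  }
  out$x[out$gap] <- NA_real_
  out$y[out$gap] <- NA_real_
  if ("participant_id" %in% names(fixes)) {
    out <- dplyr::mutate(out, participant_id = fixes$participant_id[1],
                         .before = 1)
  }
  out
}

# Constant-velocity Kalman filter for one coordinate axis. States are
# (position, velocity); Q is the continuous white-noise acceleration model.
kalman_cv <- function(t, z, process_sd, measure_sd) {
  n <- length(z)
  q <- process_sd^2
  rv <- measure_sd^2
  xhat <- c(z[1], 0)
  P <- matrix(c(rv, 0, 0, 100), 2, 2)
  out <- numeric(n)
  out[1] <- z[1]
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    A <- matrix(c(1, 0, dt, 1), 2, 2)
    Q <- q * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
    xhat <- A %*% xhat
    P <- A %*% P %*% t(A) + Q
    S <- P[1, 1] + rv
    K <- P[, 1] / S
    innov <- z[i] - xhat[1]
    xhat <- xhat + K * innov
    P <- (diag(2) - cbind(K, c(0, 0))) %*% P
    out[i] <- xhat[1]
  }
  out
}

#' Temporal weights of a trajectory
#'
#' Attributes to each visited location `i` the fraction of the total
#' trajectory duration spent there under the left-constant convention:
#' `wt_i = (t_{i+1} - t_i) / D` for `i = 1..n-1` with `D = t_n - t_1`, and
#' `wt_n = 0`, so the weights sum to one exactly. These weights turn
#' momentary exposures into a time-weighted accumulation.
#'
#' @param traj Trajectory tibble with a strictly increasing `time` column.
#' @return `traj` with a numeric `wt` column added.
#' @export
add_temporal_weights <- function(traj) {
  stopifnot(is.data.frame(traj), "time" %in% names(traj))
  tt <- as.numeric(traj$time)
  if (length(tt) < 2) abort("trajectory needs at least 2 fixes.")
  d <- diff(tt)
  if (any(d <= 0)) abort("timestamps must be strictly increasing.")
  D <- tt[length(tt)] - tt[1]
  traj$wt <- c(d / D, 0)
  traj
}
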