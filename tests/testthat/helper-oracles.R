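# Independent oracles used by the dual-route tests. These deliberately do
# not share code with the package implementation.

# Supersampling oracle for the area-weighted buffer mean: a dense regular
# grid of points over the disc's bounding square, keeping points inside the
# disc and looking pixels up with the same half-open convention the raster
# documents. Error is O(1/n_side) relative.
supersample_buffer_mean <- function(raster, cx, cy, radius, n_side = 1200) {
  h <- 2 * radius / n_side
  g <- seq(-radius + h / 2, radius - h / 2, length.out = n_side)
  px <- rep(cx + g, times = n_side)
  py <- rep(cy + g, each = n_side)
  keep <- (px - cx)^2 + (py - cy)^2 <= radius^2
  px <- px[keep]; py <- py[keep]
  p <- raster$pixel_size
  col <- floor((px - raster$origin_x) / p) + 1L
  row <- floor((raster$origin_y - py) / p) + 1L
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  inside <- row >= 1L & row <= nr & col >= 1L & col <= nc
  v <- raster$values[cbind(row[inside], col[inside])]
  mean(v, na.rm = TRUE)
}

# Independent sunrise/sunset oracle: the low-order Fourier-series solar
# position approximation (fractional-year expansion of the equation of time
# and declination), a different formulation from the package's polynomial
# ephemeris. Agreement is expected to within a few minutes.
oracle_sun_times <- function(date, lon, lat, tz_offset = 8) {
  doy <- as.integer(format(as.Date(date), "%j"))
  leap <- as.integer(format(as.Date(date), "%Y")) %% 4 == 0
  gamma <- 2 * pi / ifelse(leap, 366, 365) * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) -
                        0.032077 * sin(gamma) - 0.014615 * cos(2 * gamma) -
                        0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  rad <- pi / 180
  cos_ha <- cos(rad * 90.833) / (cos(rad * lat) * cos(decl)) -
    tan(rad * lat) * tan(decl)
  if (any(abs(cos_ha) > 1)) return(list(sunrise = NA, sunset = NA))
  ha <- acos(cos_ha) / rad
  base <- as.POSIXct(as.numeric(as.Date(date)) * 86400,
                     origin = "1970-01-01", tz = "UTC")
  list(sunrise = base + (720 - 4 * (lon + ha) - eqtime) * 60,
       sunset = base + (720 - 4 * (lon - ha) - eqtime) * 60)
}

# Closed-form t-test oracles.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  se <- sd(d) / sqrt(n)
  t <- mean(d) / se
  list(D = mean(d), SE = se, t = t, df = n - 1,
       p = 2 * pt(-abs(t), n - 1))
}

oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  se <- sqrt(va + vb)
  t <- (mean(a) - mean(b)) / se
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(D = mean(a) - mean(b), SE = se, t = t, df = df,
       p = 2 * pt(-abs(t), df))
}

# A reproducible textured test raster (strictly positive, no nodata).
toy_raster <- function(nr = 80, nc = 80, pixel = 10, seed = 7,
                       origin_x = 0) {
  withr::with_seed(seed, {
    smooth <- outer(sin(seq_len(nr) / 9), cos(seq_len(nc) / 7)) * 40 + 100
    v <- smooth * matrix(runif(nr * nc, 0.5, 1.5), nr, nc)
  })
  ntl_raster(v, origin_x = origin_x, pixel_size = pixel)
}

# A minimal nighttime trajectory: stationary at (x, y) with every fix
# flagged night and weights attached.
stationary_night_traj <- function(x, y, n = 10) {
  traj <- tibble::tibble(
    time = as.POSIXct("2021-03-22 20:00:00", tz = "UTC") +
      60 * (seq_len(n) - 1),
    x = rep(x, n), y = rep(y, n), night = TRUE)
  add_temporal_weights(traj)
}
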