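#' Sensor specification
#'
#' Describes an NTL sensor product: nominal resolution, spectral band and the
#' radiometric calibration model turning raw digital numbers (DN) into
#' spectral radiance. Two calibration families are supported:
#' a power law `L = DN^exponent / scale` (Luojia1-01 style, default exponent
#' 3/2 and scale 1e10) and an affine model `L = DN * gain + bias` (SDGSAT-1
#' style, coefficients from product metadata). Pre-calibrated products
#' (SNPP/VIIRS style) carry `calibration_kind = "precalibrated"`.
#'
#' @param name Sensor name.
#' @param nominal_resolution Nominal ground resolution, metres.
#' @param spectral_range Length-2 numeric, band limits in nm.
#' @param bandwidth Spectral bandwidth in nm (> 0).
#' @param calibration_kind `"precalibrated"`, `"power_law"` or `"gain_bias"`.
#' @param gain,bias Affine calibration coefficients (gain/bias kind).
#' @param power_exponent,power_scale Power-law coefficients.
#' @return A `sensor_spec` object.
#' @export
sensor_spec <- function(name, nominal_resolution, spectral_range, bandwidth,
                        calibration_kind = c("precalibrated", "power_law",
                                             "gain_bias"),
                        gain = NA_real_, bias = NA_real_,
                        power_exponent = 1.5, power_scale = 1e10) {
  calibration_kind <- match.arg(calibration_kind)
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    abort("`bandwidth` must be positive (nm).")
  }
  if (calibration_kind == "gain_bias" && (is.na(gain) || is.na(bias))) {
    abort("gain/bias calibration requires both `gain` and `bias`.")
  }
  if (calibration_kind == "power_law" &&
      (!is.finite(power_exponent) || !is.finite(power_scale) ||
       power_exponent <= 0 || power_scale <= 0)) {
    abort("power-law calibration requires positive exponent and scale.")
  }
  structure(
    list(name = name, nominal_resolution = nominal_resolution,
         spectral_range = spectral_range, bandwidth = bandwidth,
         calibration_kind = calibration_kind, gain = gain, bias = bias,
         power_exponent = power_exponent, power_scale = power_scale),
    class = "sensor_spec")
}

#' Built-in sensor specifications
#'
#' The three NTL products the measurement framework targets: a 10 m
#' glimmer imager with metadata gain/bias calibration, a 130 m panchromatic
#' imager with power-law calibration, and a pre-calibrated 500 m day/night
#' band mosaic.
#'
#' @param gain,bias Metadata calibration coefficients for the 10 m product.
#' @return A `sensor_spec`.
#' @export
spec_glimmer_10m <- function(gain = 1e-4, bias = 0) {
  sensor_spec("glimmer-10m", 10, c(444, 910), 466, "gain_bias",
              gain = gain, bias = bias)
}

#' @rdname spec_glimmer_10m
#' @export
spec_pan_130m <- function() {
  sensor_spec("pan-130m", 130, c(460, 980), 520, "power_law")
}

#' @rdname spec_glimmer_10m
#' @export
spec_dnb_500m <- function() {
  sensor_spec("dnb-500m", 500, c(500, 900), 400, "precalibrated")
}

check_dn_raster <- function(raster) {
  stopifnot(inherits(raster, "ntl_raster"))
  if (raster$units != "DN") {
    abort(sprintf("expected a DN raster, got units \"%s\".", raster$units))
  }
  neg <- which(!is.na(raster$values) & raster$values < 0)
  if (length(neg)) {
    abort(sprintf("negative DN at cell index %d (value %.6g).",
                  neg[1], raster$values[neg[1]]))
  }
  invisible(raster)
}

#' Power-law radiometric calibration
#'
#' Converts raw digital numbers to spectral radiance via
#' `L = DN^exponent / scale` (defaults: exponent 3/2, scale 1e10, giving
#' W m^-2 sr^-1 um^-1). Nodata cells and grid geometry are preserved.
#'
#' @param dn_raster An [ntl_raster] with `units = "DN"`.
#' @param spec A [sensor_spec] with `calibration_kind = "power_law"`.
#' @return An [ntl_raster] in `spectral_radiance` units.
#' @export
calibrate_power_law <- function(dn_raster, spec = spec_pan_130m()) {
  check_dn_raster(dn_raster)
  if (spec$calibration_kind != "power_law") {
    abort("`spec` does not describe a power-law calibrated sensor.")
  }
  v <- dn_raster$values ^ spec$power_exponent / spec$power_scale
  ntl_raster(v, dn_raster$origin_x, dn_raster$origin_y, dn_raster$pixel_size,
             dn_raster$crs, "spectral_radiance", dn_raster$nodata)
}

#' Gain/bias radiometric calibration
#'
#' Converts raw digital numbers to spectral radiance via
#' `L = DN * gain + bias`, with coefficients taken from product metadata.
#'
#' @inheritParams calibrate_power_law
#' @param spec A [sensor_spec] with `calibration_kind = "gain_bias"`.
#' @return An [ntl_raster] in `spectral_radiance` units.
#' @export
calibrate_gain_bias <- function(dn_raster, spec) {
  check_dn_raster(dn_raster)
  if (spec$calibration_kind != "gain_bias") {
    abort("`spec` does not describe a gain/bias calibrated sensor.")
  }
  if (is.na(spec$gain) || is.na(spec$bias)) {
    abort("`spec` is missing gain and/or bias coefficients.")
  }
  v <- dn_raster$values * spec$gain + spec$bias
  ntl_raster(v, dn_raster$origin_x, dn_raster$origin_y, dn_raster$pixel_size,
             dn_raster$crs, "spectral_radiance", dn_raster$nodata)
}

#' Convert spectral radiance to band radiance
#'
#' Multiplies per-micron spectral radiance (W m^-2 sr^-1 um^-1) by a single
#' conversion factor to obtain band radiance in nW cm^-2 sr^-1, the common
#' unit of all exposure estimators. The default factor is
#' `bandwidth_um * 1e5`: the band width integrates out the per-micron
#' dependence and 1 W m^-2 = 1e5 nW cm^-2. Any alternative unit convention is
#' one `factor` change.
#'
#' @param raster An [ntl_raster] in `spectral_radiance` units.
#' @param spec A [sensor_spec] supplying the bandwidth (ignored when `factor`
#'   is given).
#' @param factor Optional explicit positive conversion scalar.
#' @return An [ntl_raster] in `band_radiance` units.
#' @export
to_band_radiance <- function(raster, spec = NULL, factor = NULL) {
  stopifnot(inherits(raster, "ntl_raster"))
  if (raster$units != "spectral_radiance") {
    abort(sprintf("expected spectral_radiance units, got \"%s\".",
                  raster$units))
  }
  if (is.null(factor)) {
    if (is.null(spec)) abort("provide either `spec` or `factor`.")
    factor <- spec$bandwidth / 1000 * 1e5
  }
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    abort("conversion `factor` must be a single positive number.")
  }
  ntl_raster(raster$values * factor, raster$origin_x, raster$origin_y,
             raster$pixel_size, raster$crs, "band_radiance", raster$nodata)
}

#' Sample paired buffer-zone means from two overlapping rasters
#'
#' Draws `n` random points (seeded, uniform over the spatial overlap of the
#' two rasters) and computes, for each point, the area-weighted buffer-zone
#' mean of both rasters within `radius` metres. Points whose buffer covers no
#' valid pixel on either raster are rejected and redrawn (at most `100 * n`
#' attempts). These pairs feed [fit_cross_calibration()].
#'
#' @param reference,predictor Overlapping [ntl_raster]s.
#' @param n Number of sample points (>= 3; study default 294).
#' @param radius Buffer radius in metres (study default 1000).
#' @param seed Integer seed for point placement.
#' @return Tibble with columns `x`, `y`, `reference`, `predictor`.
#' @export
sample_buffer_pairs <- function(reference, predictor, n = 294, radius = 1000,
                                seed = 1) {
  stopifnot(inherits(reference, "ntl_raster"),
            inherits(predictor, "ntl_raster"))
  if (n < 3) abort("`n` must be at least 3.")
  if (radius <= 0) abort("`radius` must be positive.")
  e1 <- raster_extent(reference); e2 <- raster_extent(predictor)
  xmin <- max(e1["xmin"], e2["xmin"]); xmax <- min(e1["xmax"], e2["xmax"])
  ymin <- max(e1["ymin"], e2["ymin"]); ymax <- min(e1["ymax"], e2["ymax"])
  if (xmin >= xmax || ymin >= ymax) {
    abort("the two rasters do not overlap spatially.")
  }
  withr::with_seed(seed, {
    got_x <- numeric(0); got_y <- numeric(0)
    got_ref <- numeric(0); got_pred <- numeric(0)
    attempts <- 0L
    while (length(got_x) < n && attempts < 100L * n) {
      m <- min(4L * n, 100L * n - attempts)
      attempts <- attempts + m
      px <- runif(m, xmin, xmax)
      py <- runif(m, ymin, ymax)
      rv <- buffer_average(reference, px, py, radius, strict = FALSE)
      pv <- buffer_average(predictor, px, py, radius, strict = FALSE)
      ok <- !is.na(rv) & !is.na(pv)
      got_x <- c(got_x, px[ok]); got_y <- c(got_y, py[ok])
      got_ref <- c(got_ref, rv[ok]); got_pred <- c(got_pred, pv[ok])
    }
  })
  if (length(got_x) < n) {
    abort(sprintf("could only place %d of %d valid buffers.",
                  length(got_x), n))
  }
  tibble::tibble(x = got_x[seq_len(n)], y = got_y[seq_len(n)],
                 reference = got_ref[seq_len(n)],
                 predictor = got_pred[seq_len(n)])
}

#' Fit a cross-sensor linear calibration
#'
#' Ordinary-least-squares fit of reference-sensor radiance on
#' predictor-sensor radiance, `reference = slope * predictor + intercept`,
#' used to map one sensor's luminosity onto another's scale. The coefficient
#' of determination R^2 summarises cross-sensor consistency.
#'
#' @param pairs Tibble/data frame with columns `reference` and `predictor`
#'   (as produced by [sample_buffer_pairs()]).
#' @param reference,predictor Names recorded on the result.
#' @return An `ntl_calibration` object with fields `slope`, `intercept`,
#'   `r2`, `n`, `reference`, `predictor`.
#' @export
fit_cross_calibration <- function(pairs, reference = "reference",
                                  predictor = "predictor") {
  stopifnot(is.data.frame(pairs),
            all(c("reference", "predictor") %in% names(pairs)))
  if (nrow(pairs) < 3) abort("need at least 3 pairs.")
  if (var(pairs$predictor) == 0) {
    abort("degenerate predictor: all values equal, slope is unidentified.")
  }
  fit <- lm(reference ~ predictor, data = pairs)
  # summary.lm warns on exactly collinear (noise-free) input; R^2 = 1 there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = r2, n = nrow(pairs),
         reference = reference, predictor = predictor),
    class = "ntl_calibration")
}

#' @export
print.ntl_calibration <- function(x, ...) {
  cat(sprintf(
    "<ntl_calibration> %s = %.4f * %s %+.4f  (R^2 = %.3f, n = %d)\n",
    x$reference, x$slope, x$predictor, x$intercept, x$r2, x$n))
  invisible(x)
}

#' @export
tidy.ntl_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.ntl_calibration <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n,
                 reference = x$reference, predictor = x$predictor)
}

#' Apply an affine cross-calibration
#'
#' Applies `slope * x + intercept`. By design this is applied to *final
#' per-setting exposure scalars*, not to rasters: an affine map of
#' per-participant exposures rescales paired-difference statistics (D, SE)
#' by the slope while leaving t, df and p unchanged, the pattern seen when
#' comparing raw and cross-calibrated measurement rows. Raster-level
#' application is available for sensitivity analyses by passing an
#' [ntl_raster].
#'
#' @param x Numeric vector or [ntl_raster].
#' @param cal An `ntl_calibration`.
#' @return Same shape as `x`.
#' @export
apply_calibration <- function(x, cal) {
  stopifnot(inherits(cal, "ntl_calibration"))
  if (inherits(x, "ntl_raster")) {
    x$values <- cal$slope * x$values + cal$intercept
    return(x)
  }
  cal$slope * x + cal$intercept
}

#' Serialise / read a cross-calibration as JSON
#'
#' @param cal An `ntl_calibration`.
#' @param path File path.
#' @return `read_calibration()` returns an `ntl_calibration`.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "ntl_calibration"))
  jsonlite::write_json(
    list(reference = cal$reference, predictor = cal$predictor,
         slope = cal$slope, intercept = cal$intercept, r2 = cal$r2,
         n = cal$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 n = x$n, reference = x$reference, predictor = x$predictor),
            class = "ntl_calibration")
}
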