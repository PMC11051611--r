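#' Nighttime-light raster
#'
#' A lightweight container for a single-band georeferenced nighttime-light
#' (NTL) grid on a planar metric coordinate system. Values are band radiance
#' in nW cm^-2 sr^-1 once calibrated, or raw digital numbers (DN) before
#' calibration. Row 1 of `values` is the top of the raster; `origin_x`,
#' `origin_y` locate the *upper-left corner* of the grid in metres.
#'
#' Pixel extents are half-open: the pixel in row `i`, column `j` covers
#' `[x0 + (j-1)p, x0 + jp)` horizontally and `(y0 - ip, y0 - (i-1)p]`
#' vertically, so a point on a shared edge belongs to exactly one pixel.
#' Missing/cloud pixels are stored as `NA`.
#'
#' @param values Numeric matrix of pixel values (`NA` = nodata).
#' @param origin_x,origin_y Coordinates of the upper-left corner, metres.
#' @param pixel_size Pixel edge length, metres (> 0).
#' @param crs Free-text tag for the planar CRS (e.g. `"EPSG:32649"`).
#' @param units One of `"DN"`, `"spectral_radiance"` (W m^-2 sr^-1 um^-1)
#'   or `"band_radiance"` (nW cm^-2 sr^-1).
#' @param nodata Sentinel written to file for `NA` cells.
#'
#' @return An object of class `ntl_raster`.
#' @examples
#' r <- ntl_raster(matrix(1:9, 3, 3), pixel_size = 10)
#' pixel_at(r, 15, 25)
#' @export
ntl_raster <- function(values, origin_x = 0, origin_y = NULL, pixel_size = 10,
                       crs = "local-metric", units = "band_radiance",
                       nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (nrow(values) < 1 || ncol(values) < 1) {
    abort("raster must have at least one row and one column.")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number.")
  }
  units <- match.arg(units, c("band_radiance", "spectral_radiance", "DN"))
  if (is.null(origin_y)) origin_y <- nrow(values) * pixel_size
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) {
    abort(sprintf("raster contains %d non-finite non-nodata values.", sum(bad)))
  }
  structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         pixel_size = pixel_size, crs = crs, units = units, nodata = nodata),
    class = "ntl_raster"
  )
}

#' @export
print.ntl_raster <- function(x, ...) {
  ext <- raster_extent(x)
  cat(sprintf(
    "<ntl_raster> %d x %d pixels @ %g m [%s]\n  extent: x %g..%g, y %g..%g (%s)\n",
    nrow(x$values), ncol(x$values), x$pixel_size, x$units,
    ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"], x$crs))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values: mean %.4g, range %.4g..%.4g, %d nodata cells\n",
                mean(v), min(v), max(v), sum(is.na(x$values))))
  }
  invisible(x)
}

#' @export
dim.ntl_raster <- function(x) dim(x$values)

#' Raster extent
#'
#' @param raster An [ntl_raster].
#' @return Named numeric vector `xmin`, `xmax`, `ymin`, `ymax` (metres).
#' @export
raster_extent <- function(raster) {
  stopifnot(inherits(raster, "ntl_raster"))
  p <- raster$pixel_size
  c(xmin = raster$origin_x,
    xmax = raster$origin_x + ncol(raster$values) * p,
    ymin = raster$origin_y - nrow(raster$values) * p,
    ymax = raster$origin_y)
}

#' Convert a raster to a long tibble of pixel centres
#'
#' @param x An [ntl_raster].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y` (pixel centres) and `value`.
#' @export
as_tibble.ntl_raster <- function(x, ...) {
  p <- x$pixel_size
  nr <- nrow(x$values); nc <- ncol(x$values)
  cx <- rep(x$origin_x + (seq_len(nc) - 0.5) * p, each = nr)
  cy <- rep(x$origin_y - (seq_len(nr) - 0.5) * p, times = nc)
  vals <- as.vector(x$values)
  tibble::tibble(x = cx, y = cy, value = vals)
}

#' Mean of valid pixel values
#'
#' @param x An [ntl_raster].
#' @param ... Unused.
#' @export
mean.ntl_raster <- function(x, ...) mean(x$values, na.rm = TRUE)

pixel_index <- function(raster, x, y) {
  p <- raster$pixel_size
  col <- floor((x - raster$origin_x) / p) + 1L
  row <- floor((raster$origin_y - y) / p) + 1L
  # the top edge of the raster belongs to row 1 (closed top convention)
  row[!is.na(y) & y == raster$origin_y] <- 1L
  list(row = as.integer(row), col = as.integer(col))
}

#' Point query of a raster
#'
#' Returns the value of the unique pixel whose half-open extent contains each
#' point (the in-situ exposure primitive). Points outside the raster extent or
#' falling on a nodata pixel raise an error naming the offending point.
#'
#' @param raster An [ntl_raster].
#' @param x,y Point coordinates, metres (vectorised).
#' @return Numeric vector of pixel values.
#' @export
pixel_at <- function(raster, x, y) {
  stopifnot(inherits(raster, "ntl_raster"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  idx <- pixel_index(raster, x, y)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  outside <- idx$row < 1L | idx$row > nr | idx$col < 1L | idx$col > nc |
    !is.finite(x) | !is.finite(y)
  if (any(outside)) {
    i <- which(outside)[1]
    abort(sprintf("point %d (%.2f, %.2f) lies outside the raster extent.",
                  i, x[i], y[i]))
  }
  v <- raster$values[cbind(idx$row, idx$col)]
  if (anyNA(v)) {
    i <- which(is.na(v))[1]
    abort(sprintf("point %d (%.2f, %.2f) falls on a nodata pixel.",
                  i, x[i], y[i]))
  }
  v
}

#' Degrade raster resolution by block averaging
#'
#' Aggregates `factor` x `factor` blocks of pixels into one output pixel whose
#' value is the area-weighted (here: simple, as pixels share one area) mean of
#' the valid input pixels in the block. Nodata cells are excluded from both
#' numerator and denominator; an all-nodata block propagates nodata. This is
#' how a fine sensor product is resampled to emulate a coarser sensor.
#'
#' @param raster An [ntl_raster].
#' @param factor Positive integer aggregation factor.
#' @param pad `"error"` (default) rejects grids whose dimensions are not
#'   divisible by `factor`; `"nodata"` pads the right/bottom edge with nodata.
#' @return An [ntl_raster] with `pixel_size * factor`.
#' @export
degrade_resolution <- function(raster, factor, pad = c("error", "nodata")) {
  stopifnot(inherits(raster, "ntl_raster"))
  pad <- match.arg(pad)
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    abort("`factor` must be a single positive integer.")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(raster)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% factor != 0 || nc %% factor != 0) {
    if (pad == "error") {
      abort(sprintf(
        "grid %d x %d is not divisible by factor %d (use pad = \"nodata\").",
        nr, nc, factor))
    }
    nr2 <- ceiling(nr / factor) * factor
    nc2 <- ceiling(nc / factor) * factor
    v2 <- matrix(NA_real_, nr2, nc2)
    v2[seq_len(nr), seq_len(nc)] <- v
    v <- v2; nr <- nr2; nc <- nc2
  }
  gi <- rep(seq_len(nr / factor), each = factor)
  gj <- rep(seq_len(nc / factor), each = factor)
  v0 <- ifelse(is.na(v), 0, v)
  cnt <- !is.na(v)
  sums <- t(rowsum(t(rowsum(v0, gi)), gj))
  counts <- t(rowsum(t(rowsum(cnt + 0, gi)), gj))
  out <- sums / counts
  out[counts == 0] <- NA_real_
  ntl_raster(out, raster$origin_x, raster$origin_y,
             raster$pixel_size * factor, raster$crs, raster$units,
             raster$nodata)
}
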