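#' Area-weighted buffer-zone mean
#'
#' Computes the area-weighted mean of raster values over a disc of radius
#' `radius` centred at each point: `sum(value_k * a_k) / sum(a_k)` where
#' `a_k` is the exact intersection area of pixel `k` with the disc (this is
#' the area integral `int NTL da / int da`, evaluated with closed-form
#' disc-pixel intersection geometry, not a pixel-centre approximation).
#' Nodata pixels and off-raster area are excluded from both numerator and
#' denominator, so buffers straddling the raster edge renormalise over the
#' covered area.
#'
#' @param raster An [ntl_raster].
#' @param x,y Disc centre coordinates, metres (vectorised).
#' @param radius Disc radius, metres (> 0).
#' @param strict If `TRUE` (default), a disc covering no valid pixel raises
#'   an error naming the point; if `FALSE`, it yields `NA`.
#' @return Numeric vector of buffer means.
#' @export
buffer_average <- function(raster, x, y, radius, strict = TRUE) {
  stopifnot(inherits(raster, "ntl_raster"))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("`radius` must be a single positive number (metres).")
  }
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  out <- cpp_buffer_mean(raster$values, raster$origin_x, raster$origin_y,
                         raster$pixel_size, x, y, radius)
  if (strict && anyNA(out)) {
    i <- which(is.na(out))[1]
    abort(sprintf(
      "buffer at point %d (%.2f, %.2f) covers no valid pixel area.",
      i, x[i], y[i]))
  }
  out
}

#' Residence-based exposure estimators
#'
#' `rbm_in_situ()` is the pixel value of the NTL image at a participant's
#' home location; `rbm_buffer()` is the area-weighted buffer-zone mean
#' around the home. Both are vectorised over homes.
#'
#' @param raster An [ntl_raster].
#' @param home_x,home_y Home coordinates, metres.
#' @param radius Buffer radius, metres (study radii: 65, 100, 250, 300, 500).
#' @return Numeric vector of exposures (nW cm^-2 sr^-1).
#' @export
rbm_in_situ <- function(raster, home_x, home_y) {
  pixel_at(raster, home_x, home_y)
}

#' @rdname rbm_in_situ
#' @export
rbm_buffer <- function(raster, home_x, home_y, radius) {
  buffer_average(raster, home_x, home_y, radius)
}

check_traj_cols <- function(traj, need) {
  miss <- setdiff(need, names(traj))
  if (length(miss)) {
    abort(sprintf("trajectory is missing column(s): %s (run %s first).",
                  paste(miss, collapse = ", "),
                  paste(c("add_temporal_weights()",
                          "add_night_flags()")[c("wt", "night") %in% miss],
                        collapse = " and ")))
  }
}

mom_accumulate <- function(values, wt_night, night_fraction,
                           mode = c("full", "night_only")) {
  mode <- match.arg(mode)
  total <- sum(values * wt_night)
  value <- if (mode == "full") {
    total                       # daytime momentary exposures count as 0
  } else if (night_fraction > 0) {
    total / night_fraction      # renormalise over nighttime duration only
  } else {
    NA_real_
  }
  tibble::tibble(value = value, night_fraction = night_fraction)
}

#' Mobility-oriented exposure estimators
#'
#' Accumulate momentary exposures along a trajectory, weighted by the
#' fraction of the trajectory duration spent at each visited location
#' (`wt` column from [add_temporal_weights()]). Only nighttime fixes
#' (`night` column from [add_night_flags()]) contribute: daytime momentary
#' exposures to outdoor light are assigned a value of 0. Under the default
#' `mode = "full"` the weights of daytime fixes still count in the total
#' duration `D`; `mode = "night_only"` renormalises the weights over the
#' nighttime fixes (sensitivity analysis). `mom_in_situ()` samples the pixel
#' under each fix, `mom_buffer()` the buffer-zone mean around each fix.
#'
#' Fixes flagged as gaps (`NA` coordinates) contribute 0, like daytime
#' fixes. Nighttime fixes with valid coordinates must lie inside the raster
#' on valid pixels; violations raise an error naming the fix.
#'
#' @param raster An [ntl_raster].
#' @param traj Trajectory tibble with columns `x`, `y`, `wt`, `night`.
#' @param radius Buffer radius in metres (`mom_buffer()` only).
#' @param mode `"full"` (default) or `"night_only"`.
#' @return One-row tibble with `value` and `night_fraction` (the summed
#'   temporal weight of nighttime fixes).
#' @export
mom_in_situ <- function(raster, traj, mode = c("full", "night_only")) {
  check_traj_cols(traj, c("x", "y", "wt", "night"))
  use <- traj$night & !is.na(traj$x) & !is.na(traj$y)
  values <- if (any(use)) pixel_at(raster, traj$x[use], traj$y[use]) else
    numeric(0)
  mom_accumulate(values, traj$wt[use], sum(traj$wt[traj$night]), mode)
}

#' @rdname mom_in_situ
#' @export
mom_buffer <- function(raster, traj, radius, mode = c("full", "night_only")) {
  check_traj_cols(traj, c("x", "y", "wt", "night"))
  use <- traj$night & !is.na(traj$x) & !is.na(traj$y)
  if (any(use)) {
    xs <- traj$x[use]; ys <- traj$y[use]
    # repeated positions (e.g. stationary at home) are computed once
    key <- paste(xs, ys)
    uk <- !duplicated(key)
    vals_u <- buffer_average(raster, xs[uk], ys[uk], radius)
    values <- vals_u[match(key, key[uk])]
  } else {
    values <- numeric(0)
  }
  mom_accumulate(values, traj$wt[use], sum(traj$wt[traj$night]), mode)
}

#' The canonical contextual-setting grid
#'
#' The ten base measurement settings of the systematic design: in-situ
#' measurements at 500 m, 130 m and 10 m resolution (the two coarse ones
#' both raw and cross-calibrated) and buffer-zone averages on the 10 m
#' product at radii 65, 100, 250, 300 and 500 m. Crossed with the two
#' measurement approaches (mobility-oriented `M`, residence-based `R`) this
#' yields 20 labelled settings; evaluated per community they form the 40
#' measurement groups. The 65 m and 250 m radii are the fine-product
#' matches for the 130 m and 500 m in-situ footprints.
#'
#' @return Tibble with columns `setting`, `method`, `resolution`, `radius`,
#'   `cross_calibrated`.
#' @export
exposure_settings <- function() {
  tibble::tibble(
    setting = c("r500m", "r500m_CC", "r130m", "r130m_CC", "r010m",
                "b065m", "b100m", "b250m", "b300m", "b500m"),
    method = c(rep("in_situ", 5), rep("buffer", 5)),
    resolution = c(500, 500, 130, 130, 10, rep(10, 5)),
    radius = c(rep(NA_real_, 5), 65, 100, 250, 300, 500),
    cross_calibrated = c(FALSE, TRUE, FALSE, TRUE, rep(FALSE, 6))
  )
}

raster_key <- function(resolution) sprintf("r%03d", resolution)

#' Compute the full exposure measurement matrix
#'
#' Evaluates every requested contextual setting for every participant under
#' both measurement approaches, producing the long table behind the
#' 40-group systematic comparison: residence-based (`R_`) values from each
#' home location and mobility-oriented (`M_`) values from each 7-day
#' trajectory. Cross-calibrated settings apply the fitted affine calibration
#' to the final exposure scalar of the corresponding raw setting.
#'
#' @param participants Tibble with columns `participant_id`, `community`,
#'   `home_x`, `home_y`.
#' @param trajectories Named list of trajectory tibbles (one per
#'   `participant_id`), each carrying `x`, `y`, `wt`, `night`.
#' @param rasters Named list of [ntl_raster]s keyed `r010`, `r130`, `r500`.
#' @param calibrations Named list of `ntl_calibration`s keyed by the raster
#'   they map onto the fine reference (`r130`, `r500`); required only when a
#'   requested setting is cross-calibrated.
#' @param settings Setting grid as from [exposure_settings()].
#' @param mode Duration mode passed to the mobility estimators.
#' @return Tibble with columns `participant_id`, `community`, `approach`
#'   (`"M"`/`"R"`), `setting`, `label` (e.g. `"M_b065m"`), `value`,
#'   `night_fraction`.
#' @export
exposure_matrix <- function(participants, trajectories, rasters,
                            calibrations = NULL,
                            settings = exposure_settings(),
                            mode = "full") {
  stopifnot(is.data.frame(participants),
            all(c("participant_id", "community", "home_x", "home_y") %in%
                  names(participants)))
  base <- settings[!settings$cross_calibrated, ]
  for (i in seq_len(nrow(settings))) {
    s <- settings[i, ]
    key <- raster_key(s$resolution)
    if (is.null(rasters[[key]])) {
      abort(sprintf("setting %s needs raster \"%s\", which was not supplied.",
                    s$setting, key))
    }
    if (s$cross_calibrated && is.null(calibrations[[key]])) {
      abort(sprintf(
        "setting %s needs a cross-calibration for \"%s\", none supplied.",
        s$setting, key))
    }
  }
  missing_traj <- setdiff(participants$participant_id, names(trajectories))
  if (length(missing_traj)) {
    abort(sprintf("no trajectory for participant(s): %s",
                  paste(head(missing_traj, 5), collapse = ", ")))
  }

  per_participant <- purrr::map(seq_len(nrow(participants)), function(k) {
    p <- participants[k, ]
    traj <- trajectories[[p$participant_id]]
    purrr::map(seq_len(nrow(base)), function(i) {
      s <- base[i, ]
      ras <- rasters[[raster_key(s$resolution)]]
      if (s$method == "in_situ") {
        m <- mom_in_situ(ras, traj, mode = mode)
        r_val <- rbm_in_situ(ras, p$home_x, p$home_y)
      } else {
        m <- mom_buffer(ras, traj, s$radius, mode = mode)
        r_val <- rbm_buffer(ras, p$home_x, p$home_y, s$radius)
      }
      tibble::tibble(
        participant_id = p$participant_id, community = p$community,
        approach = c("M", "R"), setting = s$setting,
        value = c(m$value, r_val),
        night_fraction = c(m$night_fraction, m$night_fraction))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  # cross-calibrated settings: affine map of the final raw scalars
  cc <- settings[settings$cross_calibrated, ]
  cc_rows <- purrr::map(seq_len(nrow(cc)), function(i) {
    s <- cc[i, ]
    raw_label <- sub("_CC$", "", s$setting)
    cal <- calibrations[[raster_key(s$resolution)]]
    rows <- per_participant[per_participant$setting == raw_label, ]
    rows$setting <- s$setting
    rows$value <- apply_calibration(rows$value, cal)
    rows
  }) |> purrr::list_rbind()

  out <- dplyr::bind_rows(per_participant, cc_rows)
  out$label <- paste0(out$approach, "_", out$setting)
  ord <- exposure_settings()$setting
  out <- dplyr::arrange(out, match(.data$setting, ord),
                        dplyr::desc(.data$approach == "M"),
                        .data$participant_id)
  dplyr::relocate(out, "participant_id", "community", "approach", "setting",
                  "label", "value", "night_fraction")
}

#' Pivot the exposure matrix to wide format
#'
#' @param emat Long exposure matrix from [exposure_matrix()].
#' @return Tibble with one row per participant and one column per setting
#'   label.
#' @export
pivot_exposure <- function(emat) {
  tidyr::pivot_wider(
    dplyr::select(emat, "participant_id", "community", "label", "value"),
    names_from = "label", values_from = "value")
}
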