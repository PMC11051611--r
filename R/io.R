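#' Read / write rasters as ESRI ASCII grids
#'
#' Plain-text single-band grid interchange: the standard ESRI ASCII header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows top to bottom. Values round-trip at
#' full double precision; nodata cells are written as the raster's
#' `nodata` sentinel and read back as `NA`. The format carries no CRS, so
#' `crs` and `units` are supplied on read.
#'
#' @param path File path.
#' @param crs,units CRS tag and unit tag to attach on read.
#' @param raster An [ntl_raster] to write.
#' @return `read_raster()` returns an [ntl_raster]; `write_raster()`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path, crs = "unspecified", units = "band_radiance") {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  hdr_lines <- readLines(path, n = 6)
  hdr <- strsplit(trimws(hdr_lines), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(vapply(hdr, `[`, "", 2)))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys) || anyNA(vals[match(need, keys)])) {
    abort(sprintf(
      "%s is not a valid ESRI ASCII grid (missing/invalid header fields).",
      path))
  }
  h <- as.list(setNames(vals, keys))
  nodata <- if ("nodata_value" %in% keys) h$nodata_value else -9999
  n_hdr <- length(keys[keys %in% c(need, "nodata_value")])
  v <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(v) != h$ncols * h$nrows) {
    abort(sprintf("expected %d values, found %d.",
                  h$ncols * h$nrows, length(v)))
  }
  m <- matrix(v, nrow = h$nrows, ncol = h$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  ntl_raster(m, origin_x = h$xllcorner,
             origin_y = h$yllcorner + h$nrows * h$cellsize,
             pixel_size = h$cellsize, crs = crs, units = units,
             nodata = nodata)
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "ntl_raster"))
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$origin_x),
    sprintf("yllcorner %.10g",
            raster$origin_y - nrow(v) * raster$pixel_size),
    sprintf("cellsize %.10g", raster$pixel_size),
    sprintf("NODATA_value %.10g", raster$nodata))
  body <- apply(v, 1, function(row) paste(format(row, digits = 17,
                                                 trim = TRUE,
                                                 scientific = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%S%z")

#' Read / write trajectory fix tables
#'
#' CSV interchange for GPS fixes: columns `participant_id`, `timestamp`
#' (ISO-8601 with UTC offset) and positions (`x`/`y` metres and/or
#' `lon`/`lat` degrees). The reader validates the schema, reports
#' unparseable timestamps by row number, re-sorts fixes within each
#' participant, and returns a named list of trajectory tibbles.
#'
#' @param path CSV path.
#' @param trajectories Named list of trajectory tibbles (with `time`).
#' @return `read_trajectories()` returns a named list of tibbles.
#' @export
read_trajectories <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("participant_id", "timestamp")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste("trajectory file is missing column(s):",
                paste(miss, collapse = ", ")))
  }
  if (!any(c("x", "lon") %in% names(df))) {
    abort("trajectory file needs `x`/`y` or `lon`/`lat` columns.")
  }
  t <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (anyNA(t)) {
    abort(sprintf("unparseable timestamp at row %d: \"%s\"",
                  which(is.na(t))[1], df$timestamp[which(is.na(t))[1]]))
  }
  df$time <- t
  for (cl in intersect(c("x", "y", "lon", "lat"), names(df))) {
    df[[cl]] <- as.numeric(df[[cl]])
  }
  df <- dplyr::arrange(df, .data$participant_id, .data$time)
  out <- split(dplyr::select(tibble::as_tibble(df), -"timestamp"),
               df$participant_id)
  lapply(out, tibble::as_tibble)
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(trajectories, path) {
  df <- purrr::imap(trajectories, function(tr, id) {
    out <- tibble::tibble(participant_id = id, timestamp = iso8601(tr$time))
    for (cl in intersect(c("lon", "lat", "x", "y"), names(tr))) {
      out[[cl]] <- tr[[cl]]
    }
    out
  }) |> purrr::list_rbind()
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a participant/cohort table
#'
#' @param path CSV with at least `participant_id`, `community`, `home_x`,
#'   `home_y`; categorical covariates and `health_score` pass through.
#'   Duplicate participant ids are rejected. When a 6-point `health_score`
#'   is present a `healthy` dichotomisation (scores 1-3) is added.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("participant_id", "community", "home_x", "home_y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste("cohort file is missing column(s):",
                paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$participant_id)) {
    abort(sprintf("duplicate participant id: %s",
                  df$participant_id[duplicated(df$participant_id)][1]))
  }
  if ("health_score" %in% names(df) && !"healthy" %in% names(df)) {
    df$healthy <- df$health_score <= 3
  }
  tibble::as_tibble(df)
}

#' Read and validate a run configuration
#'
#' YAML configuration naming input paths, the requested setting labels and
#' analysis options. Validation is fail-fast: every referenced path must
#' exist and every setting label must be known before anything runs.
#'
#' @param path YAML file.
#' @return Named list with a `config_hash` attribute.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config: %s", path))
  cfg <- yaml::read_yaml(path)
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) abort(sprintf("configured path does not exist: %s", p))
  }
  if (!is.null(cfg$settings)) {
    unknown <- setdiff(cfg$settings, exposure_settings()$setting)
    if (length(unknown)) {
      abort(paste("unknown setting label(s):", paste(unknown, collapse = ", ")))
    }
  }
  attr(cfg, "config_hash") <- rlang::hash(cfg)
  cfg
}

#' Run the whole pipeline on synthetic data and write result tables
#'
#' One-call orchestration: simulate the study, compute the 40-group
#' exposure matrix, run the disparity-test battery, generate outcomes from
#' the designated true-exposure setting and run the logistic health
#' battery. All tables are written as CSV under `out_dir` together with a
#' JSON manifest recording the seed, parameters and a config hash;
#' identical seeds and parameters reproduce byte-identical tables.
#'
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param truth_label Setting whose exposure drives the simulated
#'   outcomes (default the mobility-oriented 10 m / 65 m buffer setting).
#' @param beta True outcome log-odds per 100 units.
#' @param ... Passed to [simulate_study()].
#' @return List with `study`, `exposure`, `comparisons`, `health`,
#'   `outcomes`.
#' @export
run_study <- function(seed = 1, out_dir = NULL, truth_label = "M_b065m",
                      beta = 0.8, ...) {
  study <- simulate_study(seed = seed, ...)
  emat <- exposure_matrix(study$participants, study$trajectories,
                          study$rasters, study$calibrations)
  comparisons <- run_comparison_battery(emat)
  truth <- emat[emat$label == truth_label, ]
  true_e <- setNames(truth$value, truth$participant_id)
  outcomes <- make_outcomes(study$participants, true_e,
                            outcome_model(beta = beta), seed = seed + 7L)
  health <- dplyr::left_join(outcomes, study$participants,
                             by = "participant_id")
  battery <- run_health_battery(emat, health)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(emat, file.path(out_dir, "exposure_matrix.csv"))
    readr::write_csv(pivot_exposure(emat),
                     file.path(out_dir, "exposure_wide.csv"))
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
    readr::write_csv(battery, file.path(out_dir, "health_models.csv"))
    readr::write_csv(study$participants, file.path(out_dir, "cohort.csv"))
    manifest <- list(seed = seed, truth_label = truth_label, beta = beta,
                     params = study$params,
                     calibrations = lapply(study$calibrations, unclass),
                     config_hash = rlang::hash(list(seed, truth_label,
                                                    beta, study$params)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(study = study, exposure = emat, comparisons = comparisons,
       health = battery, outcomes = outcomes)
}
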