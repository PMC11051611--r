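# nightlightr

Measuring personal exposure to outdoor artificial light at night (ALAN),
two ways — and quantifying how much the choice of measurement design
changes the answer.

## The problem

Epidemiological studies of nighttime light usually assign each person the
satellite radiance at (or around) their home. But people move: time spent
away from home at night is spent under a different nightscape, so the
residence-based number can misstate what a person actually encountered.
This is an instance of the uncertain geographic context problem: the
estimated exposure depends on how the exposure context is delineated.

`nightlightr` implements a systematic measurement framework that crosses

* **two measurement approaches** — residence-based (`R`, the exposure
  context is the home) and mobility-oriented (`M`, the context is the
  person's GPS trajectory, with momentary exposures weighted by time
  spent at each visited location and daytime momentary exposure defined
  as zero);
* **two estimator types** — *in-situ* (the nighttime-light pixel under
  the point) and *buffer-zone average* (the exact area-weighted mean of
  the radiance field over a disc, `∫ NTL dA / ∫ dA`, computed with
  closed-form disc–pixel intersection geometry rather than pixel-centre
  approximations);
* **three sensor products** — a 10 m "glimmer" product, a 130 m product
  and a 500 m product, linked by fitted affine cross-calibrations; and
* **five buffer radii** (65, 100, 250, 300, 500 m) on the fine product.

This yields ten contextual settings per approach — 20 labelled settings,
or 40 measurement groups across two contrasting communities (a bright,
dense old town `SSP` and a darker new town `TSW`). On top of the
exposure matrix sit two inference batteries: paired/Welch *t*-test
families quantifying disparities between communities, approaches,
sensors and radii, and a battery of covariate-adjusted binary logistic
models linking each exposure measurement to a dichotomised self-rated
health outcome.

Because real GPS cohorts are private, the package ships a first-class
synthetic generator: seeded community nightscapes with known mean
luminosities, multi-resolution sensor views with known affine
distortions (so cross-calibration has a recoverable ground truth),
home-anchored 1-minute trajectories with astronomically computed night
windows, survey-matched demographics, and outcomes drawn from a known
logistic model — every analysis in the package can be validated against
the generating truth.

## Worked example

```r
library(nightlightr)

# a small synthetic two-community study: 6 participants per community,
# two days of 1-minute fixes each
study <- simulate_study(seed = 7, n_per_community = 6, days = 2)
study$rasters$r010
#> <ntl_raster> 650 x 1300 pixels @ 10 m [band_radiance]
#>   extent: x 0..13000, y 0..6500 (synthetic-planar)
#>   values: mean 268.1, range 8.855..4276, 0 nodata cells

# the fitted 10 m ~ 130 m cross-calibration (generating truth:
# slope 1.47, intercept 23.14)
study$calibrations$r130
#> <ntl_calibration> glimmer-10m = 1.4712 * pan-130m +22.9350  (R^2 = 1.000, n = 294)

# the full exposure matrix: every setting x approach x participant
emat <- exposure_matrix(study$participants, study$trajectories,
                        study$rasters, study$calibrations)
dplyr::filter(emat, label %in% c("M_b065m", "R_b065m")) |>
  dplyr::group_by(label, community) |>
  dplyr::summarise(mean = mean(value), .groups = "drop")
#> # A tibble: 4 × 3
#>   label   community  mean
#>   <chr>   <chr>     <dbl>
#> 1 M_b065m SSP       122.
#> 2 M_b065m TSW        52.3
#> 3 R_b065m SSP       340.
#> 4 R_b065m TSW       142.

# disparity battery; note that cross-calibrated settings shift D and SE
# but leave t, df and p exactly unchanged (affine invariance)
battery <- run_comparison_battery(emat)
dplyr::filter(battery, family == "approach", community == "SSP") |>
  dplyr::select(pair, D, t, df, p, sig) |> head(4)
#> # A tibble: 4 × 6
#>   pair                         D     t    df       p sig
#>   <chr>                    <dbl> <dbl> <dbl>   <dbl> <chr>
#> 1 M_r500m - R_r500m        -93.6 -6.30     5 0.00148 **
#> 2 M_r500m_CC - R_r500m_CC -207.  -6.30     5 0.00148 **
#> 3 M_r130m - R_r130m       -155.  -5.25     5 0.00334 **
#> 4 M_r130m_CC - R_r130m_CC -227.  -5.25     5 0.00334 **
```

The mobility-oriented means sit far below the residence-based ones: with
daytime momentary exposure defined as zero and nights mostly spent at
home, `M ≈ night_fraction × R` plus the contribution of nighttime
outings — exactly the structural disparity the framework is designed to
measure.

`run_study()` wraps the whole pipeline (simulation → exposure matrix →
disparity battery → outcome generation → logistic battery) and writes
CSV tables plus a JSON manifest for a given seed.

## Package layout

* `ntl_raster()`, `pixel_at()`, `buffer_average()`, `degrade_resolution()`
  — raster container and exact zonal statistics (Rcpp).
* `calibrate_power_law()`, `calibrate_gain_bias()`, `to_band_radiance()`,
  `fit_cross_calibration()`, `apply_calibration()` — radiometric and
  cross-sensor calibration.
* `solar_events()`, `night_windows()`, `add_night_flags()` — NOAA solar
  position; nights run from sunset to the next sunrise, boundaries count
  as day.
* `assemble_trajectory()`, `add_temporal_weights()` — GPS preprocessing
  and duration weights.
* `rbm_*()`, `mom_*()`, `exposure_matrix()` — the exposure estimators
  and the 40-group matrix.
* `run_comparison_battery()`, `fit_health_model()`,
  `run_health_battery()` — inference (with `tidy()`/`glance()` methods).
* `make_nightscape()`, `make_multisensor()`, `make_trajectory()`,
  `simulate_study()` — the synthetic-data generator.
* `read_raster()`, `read_trajectories()`, `read_cohort()`,
  `read_run_config()`, `run_study()` — I/O and orchestration.

See the vignette in `vignettes/` for the measurement model, the
generator design and the numerical choices.
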