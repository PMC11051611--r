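#' Paired-sample t-test, table-ready
#'
#' Tests the mean within-participant difference between two measurement
#' settings: `D = mean(x - y)`, `SE = sd(x - y) / sqrt(n)`, `t = D / SE`
#' with `n - 1` degrees of freedom and a two-tailed p-value. Zero-variance
#' differences are returned as a flagged degenerate row (no t statistic)
#' rather than an error, so a battery of tests never aborts mid-run.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @param pair Label for the comparison.
#' @return One-row tibble: `pair`, `D`, `SE`, `t`, `df`, `p`, `test`,
#'   `degenerate`.
#' @export
paired_t <- function(x, y, pair = "x - y") {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 2) abort("need at least 2 pairs.")
  d <- x - y
  if (sd(d) == 0) {
    return(tibble::tibble(pair = pair, D = mean(d), SE = NA_real_,
                          t = NA_real_, df = n - 1, p = NA_real_,
                          test = "paired", degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(pair = pair, D = unname(tt$estimate),
                 SE = unname(tt$stderr), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 test = "paired", degenerate = FALSE)
}

#' Welch two-sample t-test, table-ready
#'
#' Two-sample t-test of `mean(a) - mean(b)` without assuming equal
#' variances, with Welch-Satterthwaite degrees of freedom. Used for
#' between-community contrasts where the two samples are independent.
#'
#' @param a,b Numeric vectors (each n >= 2, positive variance).
#' @param pair Label for the comparison.
#' @return One-row tibble: `pair`, `D`, `SE`, `t`, `df`, `p`, `test`,
#'   `degenerate`.
#' @export
welch_t <- function(a, b, pair = "a - b") {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs n >= 2.")
  if (var(a) == 0 && var(b) == 0) {
    abort("both samples have zero variance; Welch test undefined.")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(pair = pair, D = unname(tt$estimate[1] - tt$estimate[2]),
                 SE = unname(tt$stderr), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 test = "welch", degenerate = FALSE)
}

sig_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Run the full disparity-test battery
#'
#' Reproduces the four families of comparisons of the systematic design on
#' an exposure matrix:
#' \describe{
#'   \item{community}{Welch tests of old-town minus new-town means, one per
#'     setting label (20 rows).}
#'   \item{approach}{Paired tests of mobility-oriented minus residence-based
#'     values, per setting per community.}
#'   \item{sensor}{Paired tests across resolutions/sensors, including
#'     cross-calibrated and matched-buffer pairs, per approach per
#'     community.}
#'   \item{buffer_radius}{Paired tests across buffer radii, per approach per
#'     community.}
#' }
#' P-values are unadjusted by default, mirroring the original battery; set
#' `adjust = "BH"` (or any [stats::p.adjust] method) to add an adjusted
#' column `p_adj`.
#'
#' @param emat Exposure matrix from [exposure_matrix()].
#' @param communities Length-2 character: the contrast is
#'   `communities[1] - communities[2]` (defaults to the two communities in
#'   `emat`, first = brighter old town).
#' @param adjust Multiple-testing adjustment method, `"none"` by default.
#' @return Tibble of test rows with columns `family`, `community`, `pair`,
#'   `D`, `SE`, `t`, `df`, `p`, `sig`, `test`, `degenerate`.
#' @export
run_comparison_battery <- function(emat, communities = NULL,
                                   adjust = "none") {
  if (is.null(communities)) communities <- sort(unique(emat$community))
  if (length(communities) != 2) abort("need exactly two communities.")
  wide <- pivot_exposure(emat)
  labels <- setdiff(names(wide), c("participant_id", "community"))
  w1 <- wide[wide$community == communities[1], ]
  w2 <- wide[wide$community == communities[2], ]

  fam1 <- purrr::map(labels, function(lb) {
    welch_t(w1[[lb]], w2[[lb]], pair = lb)
  }) |> purrr::list_rbind()
  fam1$family <- "community"
  fam1$community <- paste(communities, collapse = " - ")

  base_settings <- unique(emat$setting)
  per_comm <- function(fun) {
    purrr::map(communities, fun) |> purrr::list_rbind()
  }

  fam2 <- per_comm(function(cm) {
    w <- wide[wide$community == cm, ]
    rows <- purrr::map(base_settings, function(s) {
      m <- paste0("M_", s); r <- paste0("R_", s)
      paired_t(w[[m]], w[[r]], pair = paste(m, "-", r))
    }) |> purrr::list_rbind()
    rows$community <- cm
    rows
  })
  fam2$family <- "approach"

  sensor_pairs <- list(
    c("r010m", "r130m"), c("r130m", "r500m"), c("b065m", "r130m"),
    c("b250m", "r500m"), c("r010m", "r130m_CC"), c("b065m", "r130m_CC"),
    c("b250m", "r500m_CC"))
  fam3 <- per_comm(function(cm) {
    w <- wide[wide$community == cm, ]
    rows <- purrr::map(c("M", "R"), function(ap) {
      purrr::map(sensor_pairs, function(pr) {
        a <- paste0(ap, "_", pr[1]); b <- paste0(ap, "_", pr[2])
        if (!all(c(a, b) %in% labels)) return(NULL)
        paired_t(w[[a]], w[[b]], pair = paste(a, "-", b))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    rows$community <- cm
    rows
  })
  fam3$family <- "sensor"

  radius_pairs <- list(c("b500m", "b300m"), c("b300m", "b100m"))
  fam4 <- per_comm(function(cm) {
    w <- wide[wide$community == cm, ]
    rows <- purrr::map(c("M", "R"), function(ap) {
      purrr::map(radius_pairs, function(pr) {
        a <- paste0(ap, "_", pr[1]); b <- paste0(ap, "_", pr[2])
        if (!all(c(a, b) %in% labels)) return(NULL)
        paired_t(w[[a]], w[[b]], pair = paste(a, "-", b))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    rows$community <- cm
    rows
  })
  fam4$family <- "buffer_radius"

  out <- dplyr::bind_rows(fam1, fam2, fam3, fam4)
  out$sig <- sig_stars(out$p)
  if (adjust != "none") out$p_adj <- stats::p.adjust(out$p, method = adjust)
  dplyr::relocate(out, "family", "community", "pair", "D", "SE", "t", "df",
                  "p", "sig", "test", "degenerate")
}

#' Adjusted binary logistic exposure-health model
#'
#' Maximum-likelihood logistic regression of the dichotomised health
#' outcome (`healthy`) on one exposure measurement, adjusted for
#' socio-demographic confounders (dummy-coded factors). The exposure is
#' scaled (default per 100 nW cm^-2 sr^-1) so the log-odds coefficient is
#' readable. Non-convergence and quasi-separation are detected and flagged,
#' never silently accepted.
#'
#' @param data Data frame with the outcome column, the exposure column and
#'   the covariate columns.
#' @param exposure Name of the exposure column (default `"value"`).
#' @param outcome Name of the logical/0-1 outcome column.
#' @param covariates Character vector of adjustment variables present in
#'   `data`. Socio-economic status is operationalised as `income_group`.
#' @param scale Exposure divisor (default 100 units per coefficient unit).
#' @return An object of class `alan_logit`; see [tidy()] and [glance()]
#'   methods, or `health_effect()` for the one-row summary.
#' @export
fit_health_model <- function(data, exposure = "value", outcome = "healthy",
                             covariates = c("age_group", "gender",
                                            "income_group",
                                            "education_group",
                                            "marital_group"),
                             scale = 100) {
  miss <- setdiff(c(exposure, outcome, covariates), names(data))
  if (length(miss)) {
    abort(paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  y <- as.logical(data[[outcome]])
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("outcome has a single class; the model is unidentifiable.")
  }
  df <- data.frame(.y = y, .e = data[[exposure]] / scale)
  for (cv in covariates) df[[cv]] <- factor(data[[cv]])
  n_par <- 2 + sum(vapply(covariates,
                          function(cv) max(nlevels(df[[cv]]) - 1, 0),
                          numeric(1)))
  if (nrow(df) <= n_par) abort("fewer observations than model parameters.")
  form <- stats::as.formula(paste(".y ~ .e",
                                  paste(c("", covariates), collapse = " + ")))
  fit <- suppressWarnings(glm(form, family = binomial(), data = df))
  eta <- predict(fit, type = "link")
  separation <- any(abs(eta) > 15)
  est <- coef(fit)[".e"]
  se <- sqrt(diag(stats::vcov(fit))[".e"])
  structure(
    list(fit = fit, beta = unname(est), se = unname(se),
         z = unname(est / se),
         ci_low = unname(est - qnorm(0.975) * se),
         ci_high = unname(est + qnorm(0.975) * se),
         p = unname(2 * pnorm(-abs(est / se))),
         n = nrow(df), scale = scale, covariates = covariates,
         converged = fit$converged, separation = separation),
    class = "alan_logit")
}

#' @export
print.alan_logit <- function(x, ...) {
  cat(sprintf(
    "<alan_logit> exposure log-odds per %g units: %.4f [%.4f, %.4f], p = %.4g (n = %d)\n",
    x$scale, x$beta, x$ci_low, x$ci_high, x$p, x$n))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$separation) cat("  WARNING: quasi-separation detected\n")
  invisible(x)
}

#' @export
tidy.alan_logit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.alan_logit <- function(x, ...) {
  tibble::tibble(nobs = x$n, converged = x$converged,
                 separation = x$separation, exposure_scale = x$scale,
                 deviance = x$fit$deviance, aic = x$fit$aic)
}

#' One-row summary of a fitted exposure-health model
#'
#' @param model An `alan_logit`.
#' @return Tibble with the exposure effect (`logit`), Wald 95% CI, z, p,
#'   n and diagnostic flags.
#' @export
health_effect <- function(model) {
  stopifnot(inherits(model, "alan_logit"))
  tibble::tibble(logit = model$beta, se = model$se, z = model$z,
                 ci_low = model$ci_low, ci_high = model$ci_high,
                 p = model$p, n = model$n, scale = model$scale,
                 converged = model$converged, separation = model$separation)
}

#' Run the logistic health-model battery
#'
#' Fits one adjusted binary logistic model per measurement setting per
#' community (the 40-model battery): dichotomised health on the setting's
#' exposure values plus socio-demographic covariates. Returns a
#' forest-plot-ready table of log-odds effects with 95% confidence
#' intervals.
#'
#' @param emat Exposure matrix from [exposure_matrix()].
#' @param health Tibble keyed by `participant_id` with the `healthy`
#'   outcome and the covariate columns.
#' @inheritParams fit_health_model
#' @return Tibble with one row per `label` x `community`.
#' @export
run_health_battery <- function(emat, health,
                               covariates = c("age_group", "gender",
                                              "income_group",
                                              "education_group",
                                              "marital_group"),
                               scale = 100) {
  joined <- dplyr::inner_join(emat, health, by = "participant_id",
                              suffix = c("", "_cohort"))
  cells <- dplyr::distinct(joined, .data$label, .data$community)
  purrr::map(seq_len(nrow(cells)), function(i) {
    cell <- joined[joined$label == cells$label[i] &
                     joined$community == cells$community[i], ]
    res <- health_effect(fit_health_model(cell, covariates = covariates,
                                          scale = scale))
    dplyr::bind_cols(tibble::tibble(label = cells$label[i],
                                    community = cells$community[i]), res)
  }) |> purrr::list_rbind()
}
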