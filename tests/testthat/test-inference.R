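test_that("paired_t matches the closed-form oracle", {
  withr::with_seed(8, {
    x <- rnorm(40, 10, 3); y <- rnorm(40, 9, 3)
  })
  got <- paired_t(x, y, pair = "x - y")
  want <- oracle_paired_t(x, y)
  expect_equal(got$D, want$D, tolerance = 1e-12)
  expect_equal(got$SE, want$SE, tolerance = 1e-12)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_false(got$degenerate)
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("zero-variance differences give a flagged degenerate row", {
  got <- paired_t(c(1, 2, 3), c(0, 1, 2))
  expect_true(got$degenerate)
  expect_equal(got$D, 1)
  expect_true(is.na(got$t))
  expect_true(is.na(got$p))
})

test_that("welch_t matches the closed-form oracle", {
  withr::with_seed(9, {
    a <- rnorm(30, 5, 2); b <- rnorm(50, 4, 5)
  })
  got <- welch_t(a, b)
  want <- oracle_welch_t(a, b)
  expect_equal(got$D, want$D, tolerance = 1e-12)
  expect_equal(got$SE, want$SE, tolerance = 1e-12)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_error(welch_t(1, 1:5), "n >= 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

# a synthetic exposure matrix with the full label set
synthetic_emat <- function(n = 8, seed = 10) {
  labels <- as.vector(outer(c("M_", "R_"), exposure_settings()$setting,
                            paste0))
  withr::with_seed(seed, {
    purrr::map(c("SSP", "TSW"), function(cm) {
      base <- if (cm == "SSP") 300 else 200
      purrr::map(labels, function(lb) {
        tibble::tibble(
          participant_id = sprintf("%s_%02d", cm, seq_len(n)),
          community = cm,
          approach = substr(lb, 1, 1),
          setting = sub("^[MR]_", "", lb),
          label = lb,
          value = rnorm(n, base, 40),
          night_fraction = 0.5)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
}

test_that("run_comparison_battery produces the four families", {
  emat <- synthetic_emat()
  out <- run_comparison_battery(emat)
  expect_equal(nrow(out), 20 + 20 + 28 + 8)
  expect_equal(as.integer(table(out$family)[c("community", "approach",
                                              "sensor", "buffer_radius")]),
               c(20L, 20L, 28L, 8L))
  # community family equals a direct Welch test on the wide columns
  wide <- pivot_exposure(emat)
  a <- wide$M_b065m[wide$community == "SSP"]
  b <- wide$M_b065m[wide$community == "TSW"]
  want <- oracle_welch_t(a, b)
  row <- out[out$family == "community" & out$pair == "M_b065m", ]
  expect_equal(row$t, want$t, tolerance = 1e-12)
  expect_equal(row$df, want$df, tolerance = 1e-12)
  # approach family equals a direct paired test within community
  m <- wide$M_r010m[wide$community == "TSW"]
  r <- wide$R_r010m[wide$community == "TSW"]
  wantp <- oracle_paired_t(m, r)
  rowp <- out[out$family == "approach" & out$community == "TSW" &
                out$pair == "M_r010m - R_r010m", ]
  expect_equal(rowp$t, wantp$t, tolerance = 1e-12)
  expect_error(run_comparison_battery(emat, communities = "SSP"),
               "two communities")
})

test_that("significance stars and BH adjustment are applied", {
  emat <- synthetic_emat()
  out <- run_comparison_battery(emat, adjust = "BH")
  expect_true("p_adj" %in% names(out))
  expect_equal(out$p_adj, p.adjust(out$p, method = "BH"))
  expect_true(all(out$sig[!is.na(out$p) & out$p < 0.01] == "**"))
  expect_true(all(out$sig[!is.na(out$p) & out$p >= 0.05] == ""))
})

# covariate-rich logistic test data with known generating coefficients
logit_data <- function(n = 400, beta = 0.6, seed = 12) {
  withr::with_seed(seed, {
    df <- tibble::tibble(
      value = rnorm(n, 300, 100),
      age_group = sample(c("18-24", "25-44", "45-64"), n, replace = TRUE),
      gender = sample(c("male", "female"), n, replace = TRUE),
      income_group = sample(c("low", "middle", "high"), n, replace = TRUE),
      education_group = sample(c("low", "middle", "high"), n,
                               replace = TRUE),
      marital_group = sample(c("single", "married", "other"), n,
                             replace = TRUE))
    lp <- 0.5 + beta * (df$value - 300) / 100 +
      0.4 * (df$gender == "female")
    df$healthy <- runif(n) < plogis(lp)
  })
  df
}

test_that("fit_health_model matches a hand-built glm", {
  df <- logit_data()
  m <- fit_health_model(df)
  ref <- glm(healthy ~ I(value / 100) + factor(age_group) + factor(gender) +
               factor(income_group) + factor(education_group) +
               factor(marital_group), family = binomial(), data = df)
  expect_equal(m$beta, unname(coef(ref)["I(value/100)"]), tolerance = 1e-8)
  expect_equal(m$se,
               unname(sqrt(diag(vcov(ref))["I(value/100)"])),
               tolerance = 1e-8)
  expect_equal(m$z, m$beta / m$se, tolerance = 1e-12)
  expect_equal(m$p, 2 * pnorm(-abs(m$z)), tolerance = 1e-12)
  expect_equal(m$ci_low, m$beta - qnorm(0.975) * m$se, tolerance = 1e-12)
  expect_true(m$converged)
  expect_false(m$separation)
  expect_equal(m$n, 400)
})

test_that("health model guards against bad inputs", {
  df <- logit_data(60)
  expect_error(fit_health_model(df[, -1]), "missing column")
  one <- df; one$healthy <- TRUE
  expect_error(fit_health_model(one), "single class")
  expect_error(fit_health_model(df[1:10, ]), "fewer observations")
})

test_that("quasi-separation is detected and flagged", {
  df <- logit_data(200)
  df$healthy <- df$value > 300      # perfectly separable in the exposure
  m <- fit_health_model(df)
  expect_true(m$separation)
})

test_that("alan_logit methods expose broom-style summaries", {
  df <- logit_data()
  m <- fit_health_model(df)
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "std.error", "statistic",
                    "p.value") %in% names(td)))
  expect_true(".e" %in% td$term)
  gl <- glance(m)
  expect_equal(gl$nobs, 400)
  expect_identical(gl$converged, TRUE)
  he <- health_effect(m)
  expect_equal(he$logit, m$beta)
  expect_output(print(m), "log-odds")
})

test_that("run_health_battery fits one model per label and community", {
  emat <- synthetic_emat(n = 60)
  ids <- unique(emat$participant_id)
  withr::with_seed(14, {
    health <- tibble::tibble(
      participant_id = ids,
      healthy = runif(length(ids)) < 0.7,
      age_group = sample(c("18-24", "25-44", "45-64"), length(ids),
                         replace = TRUE),
      gender = sample(c("male", "female"), length(ids), replace = TRUE),
      income_group = sample(c("low", "middle", "high"), length(ids),
                            replace = TRUE),
      education_group = sample(c("low", "middle", "high"), length(ids),
                               replace = TRUE),
      marital_group = sample(c("single", "married", "other"), length(ids),
                             replace = TRUE))
  })
  out <- run_health_battery(emat, health)
  expect_equal(nrow(out), 40)
  expect_setequal(unique(out$community), c("SSP", "TSW"))
  expect_true(all(is.finite(out$logit)))
  expect_true(all(out$n == 60))
  # one cell equals a direct fit
  cell <- dplyr::inner_join(emat, health, by = "participant_id")
  cell <- cell[cell$label == "M_b065m" & cell$community == "SSP", ]
  direct <- fit_health_model(cell)
  row <- out[out$label == "M_b065m" & out$community == "SSP", ]
  expect_equal(row$logit, direct$beta, tolerance = 1e-10)
  expect_equal(row$z, direct$z, tolerance = 1e-10)
})
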