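test_that("the sinusoid seasonal-risk term takes its defining values", {
  expect_equal(seasonal_risk_term(3, 3), 1)
  expect_equal(seasonal_risk_term(9, 3), -1)
  expect_equal(seasonal_risk_term(2, 11), 0, tolerance = 1e-12)
  expect_equal(seasonal_risk_term(8, 11), 0, tolerance = 1e-12)
  # M_max = 4 shifts the peak forward one month
  expect_equal(seasonal_risk_term(4, 4), 1)
  expect_equal(seasonal_risk_term(10, 4), -1)
  expect_true(all(abs(seasonal_risk_term(1:12, 7)) <= 1))
  expect_error(seasonal_risk_term(13, 3), "1..12")
  expect_error(seasonal_risk_term(3, 0), "1..12")
})

test_that("peak-month scan is antisymmetric under a six-month shift", {
  cases <- simulate_registry(sim_config(n_cases = 2000, seed = 81,
                                        seasonal_loghr = log(1.4)))
  sc <- scan_peak_month(cases, 36, covariates = "age")
  g <- sc$grid
  expect_equal(g$beta1[1:6], -g$beta1[7:12], tolerance = 1e-10)
  expect_equal(g$hr[1:6] * g$hr[7:12], rep(1, 6), tolerance = 1e-10)
  expect_equal(g$p[1:6], g$p[7:12], tolerance = 1e-8)
})

test_that("the scan recovers an injected peak-risk month", {
  cases <- simulate_registry(sim_config(n_cases = 15000, seed = 83,
                                        seasonal_loghr = 0.25,
                                        mortality_peak_month = 5))
  sc <- scan_peak_month(cases, 36)
  expect_equal(sc$best_m_max, 5)
  best <- sc$grid[sc$grid$m_max == 5, ]
  # month-resolution grouping attenuates the coefficient slightly, so
  # the check is a broad recovery band rather than the model's own CI
  expect_lt(abs(best$beta1 - 0.25), 0.1)
  expect_lt(best$p, 1e-6)
})

test_that("winter-vs-summer model recovers a north-only injected effect", {
  cty <- registry_counties()
  north <- cty[cty$latitude >= 38.05, ]; north$weight <- north$weight / sum(north$weight)
  south <- cty[cty$latitude < 38.05, ];  south$weight <- south$weight / sum(south$weight)
  cn <- simulate_registry(sim_config(n_cases = 15000, seed = 85,
                                     season_form = "winter",
                                     seasonal_loghr = log(1.35),
                                     counties = north))
  cs <- simulate_registry(sim_config(n_cases = 15000, seed = 86,
                                     season_form = "winter",
                                     seasonal_loghr = 0, counties = south))
  cases <- rbind(cn, cs)
  cases$case_id <- sprintf("case%06d", seq_len(nrow(cases)))
  cases <- assign_strata(cases)
  fn <- season_hr(cases[cases$north_south == "north", ], 36)
  fs <- season_hr(cases[cases$north_south == "south", ], 36)
  expect_gt(fn$hr_ci["winter", "lower"], 1)          # CI excludes 1 in the north
  expect_gt(1, fs$hr_ci["winter", "lower"])          # CI covers 1 in the south
  expect_lt(1, fs$hr_ci["winter", "upper"])
})

test_that("relabelling the season indicator gives the reciprocal hazard ratio", {
  cases <- make_survival(simulate_registry(
    sim_config(n_cases = 4000, seed = 87, season_form = "winter",
               seasonal_loghr = log(1.3))), 36)
  d <- encode_covariates(cases, covariates = "age")
  winter <- as.numeric(cases$month_dx %in% c(9:12, 1:2))
  fw <- fit_cox(design_add_term(d, season = winter))
  fsu <- fit_cox(design_add_term(d, season = 1 - winter))
  expect_equal(fw$hr[["season"]], 1 / fsu$hr[["season"]], tolerance = 1e-8)
  expect_equal(fw$p[["season"]], fsu$p[["season"]], tolerance = 1e-8)
})

test_that("an all-summer stratum is rejected as a constant covariate", {
  cases <- simulate_registry(sim_config(n_cases = 500, seed = 88))
  cases$month_dx <- sample(3:8, 500, replace = TRUE)
  cases$event <- "death"
  expect_error(season_hr(cases, 36), "constant covariate")
  expect_error(season_hr(cases[0, ], 36), "empty stratum")
})

test_that("latitude interaction recovers an injected per-10-degree effect", {
  cases <- simulate_registry(sim_config(
    n_cases = 15000, seed = 89, seasonal_loghr = 0,
    latitude_interaction_loghr = 0.3, mortality_peak_month = 11))
  fit <- latitude_interaction(cases, 36, season = "x1", m_max = 11)
  ci <- confint(fit)["season_x_lat10", ]
  expect_gt(0.3, ci[1]); expect_lt(0.3, ci[2])
  expect_gt(ci[1], 0)                                # excludes zero
})

test_that("shifting all latitudes moves the season main effect, not the interaction", {
  cases <- simulate_registry(sim_config(n_cases = 8000, seed = 91,
                                        seasonal_loghr = 0.1,
                                        latitude_interaction_loghr = 0.2))
  f1 <- latitude_interaction(cases, 36, season = "x1", m_max = 11)
  shifted <- cases; shifted$county_latitude <- shifted$county_latitude + 5
  f2 <- latitude_interaction(shifted, 36, season = "x1", m_max = 11)
  expect_equal(f1$coefficients[["season_x_lat10"]],
               f2$coefficients[["season_x_lat10"]], tolerance = 1e-6)
  expect_gt(abs(f1$coefficients[["season"]] - f2$coefficients[["season"]]), 0.01)
})

test_that("constant latitude makes the interaction collinear and is flagged", {
  cases <- simulate_registry(sim_config(n_cases = 1000, seed = 93))
  cases$county_latitude <- 40
  expect_error(latitude_interaction(cases, 36), "rank deficient|collinear|constant")
  cases$county_latitude[1] <- NA
  expect_error(latitude_interaction(cases, 36), "latitude")
})

test_that("3- and 5-year horizons agree in direction for a strong effect", {
  cases <- simulate_registry(sim_config(n_cases = 12000, seed = 95,
                                        season_form = "winter",
                                        seasonal_loghr = log(1.5)))
  f36 <- season_hr(cases, 36)
  f60 <- season_hr(cases, 60)
  expect_gt(f36$coefficients[["winter"]], 0)
  expect_gt(f60$coefficients[["winter"]], 0)
})
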