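test_that("horizon censoring truncates time and events correctly", {
  cases <- toy_cases(3,
                     survival_months = c(40, 12, 20),
                     event = c("death", "death", "censored"))
  s <- make_survival(cases, 36)
  expect_equal(s$time, c(36, 12, 20))
  expect_equal(s$status, c(0L, 1L, 0L))
  cases$survival_months[1] <- -1
  expect_error(make_survival(cases, 36), "non-negative")
})

test_that("covariate encoding produces k-1 treatment dummies and products", {
  cases <- make_survival(toy_cases(8,
    stage = rep(c("I", "II", "III", "IV"), 2),
    sex = rep(c("male", "female"), 4),
    survival_months = 1:8, event = rep("death", 8)), 36)
  d <- encode_covariates(cases)
  expect_equal(sum(startsWith(colnames(d$X), "stage=")), 3L)  # 4 levels -> 3 dummies
  expect_equal(sum(startsWith(colnames(d$X), "histology=")), 5L)
  expect_equal(unname(d$X[, "sex=female"]), rep(c(0, 1), 4))
  # interaction column is the elementwise product of its parents
  winter <- as.numeric(cases$month_dx %in% c(9:12, 1:2))
  lat10 <- cases$county_latitude / 10
  d2 <- design_add_term(d, winter = winter, lat10 = lat10,
                        winter_x_lat10 = winter * lat10)
  expect_equal(unname(d2$X[, "winter_x_lat10"]),
               unname(d2$X[, "winter"] * d2$X[, "lat10"]))
  # unseen factor level is refused by name
  bad <- cases; bad$stage[1] <- "V"
  expect_error(encode_covariates(bad), "V")
})

test_that("design decoding round-trips the original labels", {
  cases <- make_survival(simulate_registry(sim_config(n_cases = 200, seed = 31)), 36)
  d <- encode_covariates(cases)
  # invert the treatment coding
  stage_cols <- paste0("stage=", c("II", "III", "IV"))
  dec <- rep("I", nrow(cases))
  for (sc in stage_cols) dec[d$X[, sc] == 1] <- sub("stage=", "", sc)
  expect_equal(dec, cases$stage)
  sex_dec <- ifelse(d$X[, "sex=female"] == 1, "female", "male")
  expect_equal(sex_dec, cases$sex)
})

test_that("Newton-Raphson matches direct maximization of the enumerated partial likelihood", {
  time <- c(5, 8, 2, 12, 3, 9, 7, 1)
  status <- c(1, 0, 1, 1, 0, 1, 1, 1)
  x <- c(0.3, -1.2, 0.8, 1.5, -0.4, 0.1, -0.9, 0.6)
  d <- design_from(time, status, x = x)
  fit <- fit_cox(d, tol = 1e-10)
  direct <- optimize(function(b) enumerated_partial_loglik(b, time, status, x),
                     c(-5, 5), maximum = TRUE, tol = 1e-8)
  expect_equal(unname(coef(fit)), direct$maximum, tolerance = 1e-4)
  expect_equal(fit$loglik[["final"]], direct$objective, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("Efron and Breslow coincide exactly without ties", {
  s <- sim_surv1(300, beta = 0.5, seed = 41)
  d <- design_from(s$time, s$status, x = s$x)
  fe <- fit_cox(d, ties = "efron")
  fb <- fit_cox(d, ties = "breslow")
  expect_equal(coef(fe), coef(fb), tolerance = 1e-12)
  expect_equal(fe$se, fb$se, tolerance = 1e-12)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-12)
})

test_that("fitter agrees with survival::coxph under heavy ties", {
  skip_if_not_installed("survival")
  cases <- make_survival(simulate_registry(
    sim_config(n_cases = 3000, seed = 43, seasonal_loghr = log(1.3))), 36)
  d <- design_add_term(encode_covariates(cases),
                       seasonal_risk = seasonal_risk_term(cases$month_dx, 11))
  for (tie in c("efron", "breslow")) {
    mine <- fit_cox(d, ties = tie)
    df <- data.frame(time = d$time, status = d$status, d$X, check.names = TRUE)
    ref <- survival::coxph(survival::Surv(time, status) ~ ., data = df,
                           ties = tie)
    expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
    expect_equal(as.numeric(logLik(mine)), as.numeric(logLik(ref)),
                 tolerance = 1e-7)
  }
})

test_that("a strong simulated hazard ratio is recovered within its CI", {
  s <- sim_surv1(20000, beta = log(2), seed = 47)
  fit <- fit_cox(design_from(s$time, s$status, x = s$x))
  ci <- confint(fit)
  expect_gt(log(2), ci[1, 1])
  expect_lt(log(2), ci[1, 2])
  expect_equal(unname(fit$hr), 2, tolerance = 0.1)
})

test_that("a covariate independent of the hazard gives null results", {
  set.seed(53)
  pvals <- replicate(40, {
    n <- 250
    x <- rnorm(n)
    tt <- rexp(n, rate = 0.05)
    d <- design_from(pmin(tt, 30), as.integer(tt <= 30), x = x)
    fit_cox(d)$p[[1]]
  })
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals), 0.3); expect_lt(mean(pvals), 0.7)
})

test_that("partial log-likelihood at the optimum dominates beta = 0", {
  for (seed in c(61, 62, 63)) {
    s <- sim_surv1(400, beta = runif(1, -1, 1), seed = seed)
    fit <- fit_cox(design_from(s$time, s$status, x = s$x))
    expect_gte(fit$loglik[["final"]], fit$loglik[["null"]])
  }
})

test_that("rescaling a covariate rescales beta and preserves the Wald p", {
  s <- sim_surv1(1000, beta = 0.4, seed = 67)
  f1 <- fit_cox(design_from(s$time, s$status, x = s$x))
  f10 <- fit_cox(design_from(s$time, s$status, x = s$x * 10))
  expect_equal(unname(coef(f10)), unname(coef(f1)) / 10, tolerance = 1e-6)
  expect_equal(f10$p, f1$p, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate designs are refused with diagnosis", {
  cases <- make_survival(toy_cases(6, survival_months = 1:6,
                                   event = rep("censored", 6)), 36)
  d <- design_add_term(encode_covariates(cases, covariates = "age"),
                       z = rnorm(6))
  expect_error(fit_cox(d), "no events")
  cases$event <- "death"
  d2 <- encode_covariates(make_survival(cases, 36), covariates = "age")
  expect_error(fit_cox(d2), "constant covariate")     # age is constant in toy_cases
  d3 <- design_add_term(design_from(1:6, rep(1L, 6), x = c(1, 3, 2, 5, 4, 6)),
                        y = 2 * c(1, 3, 2, 5, 4, 6))
  expect_error(fit_cox(d3), "rank deficient|collinear")
})

test_that("cox_loglik exposes the same likelihood the fitter maximizes", {
  s <- sim_surv1(100, beta = 0.7, seed = 71)
  d <- design_from(s$time, s$status, x = s$x)
  fit <- fit_cox(d)
  expect_equal(cox_loglik(d, coef(fit)), fit$loglik[["final"]], tolerance = 1e-10)
  expect_equal(cox_loglik(d, 0), fit$loglik[["null"]], tolerance = 1e-10)
  b <- coef(fit) + 0.1
  expect_lt(cox_loglik(d, b), fit$loglik[["final"]])
})
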