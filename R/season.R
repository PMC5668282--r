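# Seasonal mortality models: winter/summer contrast, sinusoid
# seasonal-risk term, peak-month scan, latitude interaction.

#' Sinusoid seasonal-risk term
#'
#' \deqn{x_1 = \cos\!\big(2\pi (M - M_{max})/12\big)}
#' where `M` is the month of diagnosis and `M_max` the hypothesized
#' peak-risk month. The term is +1 when diagnosis falls in the
#' peak-risk month, -1 six months later, and 0 at the quarter points
#' (e.g. February and August when `M_max = 11`).
#'
#' @param M Month(s) of diagnosis, integers in 1--12.
#' @param M_max Peak-risk month, integer in 1--12.
#' @return Numeric vector in \[-1, 1\].
#' @export
seasonal_risk_term <- function(M, M_max) {
  if (any(!M %in% 1:12) || !all(M_max %in% 1:12))
    stop("months must be integers in 1..12")
  cos(2 * pi * (M - M_max) / 12)
}

.build_design <- function(cases, horizon, covariates, references) {
  cases <- make_survival(cases, horizon)
  list(cases = cases,
       design = encode_covariates(cases, covariates = covariates,
                                  references = references))
}

#' Winter-vs-summer mortality hazard ratio
#'
#' Fits the mortality Cox model with a dichotomous season-of-diagnosis
#' covariate: winter (September--February) = 1, summer (March--August)
#' = 0, adjusted for the registry risk factors (age, histology, year,
#' sex, stage). The reported term `winter` is the hazard ratio for
#' death within the horizon after a winter versus a summer diagnosis.
#'
#' @param cases Case data frame; filter to a stratum (e.g. the
#'   northern half of counties) before calling.
#' @param horizon_months Follow-up horizon, 36 or 60 typically.
#' @param scheme [stratum_scheme()] supplying the winter month set.
#' @param covariates,references Passed to [encode_covariates()].
#' @param ... Passed to [fit_cox()].
#' @return A `cox_fit`; the season term is the column `winter`.
#' @export
season_hr <- function(cases, horizon_months = 36, scheme = stratum_scheme(),
                      covariates = c("age", "histology", "year", "sex", "stage"),
                      references = .default_references, ...) {
  if (nrow(cases) == 0L) stop("empty stratum")
  b <- .build_design(cases, horizon_months, covariates, references)
  winter <- as.numeric(b$cases$month_dx %in% scheme$winter_months)
  fit_cox(design_add_term(b$design, winter = winter), ...)
}

#' Scan candidate peak-risk months for the sinusoid seasonal term
#'
#' Replaces the dichotomous season covariate by the sinusoid term
#' [seasonal_risk_term()] and refits the Cox model once for each
#' candidate peak-risk month `M_max` in 1..12, recording the seasonal
#' coefficient, hazard ratio, CI and Wald p for each. The selected
#' peak-risk month `best_m_max` maximizes the seasonal coefficient.
#' Because the covariate flips sign exactly when `M_max` shifts by six
#' months, the scan satisfies `beta1(m) = -beta1(m + 6)` and
#' `HR(m) * HR(m + 6) = 1` on any dataset.
#'
#' @inheritParams season_hr
#' @param m_grid Candidate peak months; default `1:12`.
#' @return A `season_scan` object: `grid` (data frame with columns
#'   `m_max`, `beta1`, `se`, `hr`, `hr_lower`, `hr_upper`, `p`,
#'   `loglik`), `best_m_max`, and `fits` (the underlying `cox_fit`s).
#' @export
scan_peak_month <- function(cases, horizon_months = 36,
                            covariates = c("age", "histology", "year",
                                           "sex", "stage"),
                            references = .default_references,
                            m_grid = 1:12, ...) {
  b <- .build_design(cases, horizon_months, covariates, references)
  month <- b$cases$month_dx
  fits <- lapply(m_grid, function(m) {
    x1 <- seasonal_risk_term(month, m)
    fit_cox(design_add_term(b$design, seasonal_risk = x1), ...)
  })
  grid <- do.call(rbind, lapply(seq_along(m_grid), function(i) {
    f <- fits[[i]]
    data.frame(m_max = m_grid[i],
               beta1 = f$coefficients[["seasonal_risk"]],
               se = f$se[["seasonal_risk"]],
               hr = f$hr[["seasonal_risk"]],
               hr_lower = f$hr_ci["seasonal_risk", "lower"],
               hr_upper = f$hr_ci["seasonal_risk", "upper"],
               p = f$p[["seasonal_risk"]],
               loglik = f$loglik[["final"]])
  }))
  structure(list(grid = grid,
                 best_m_max = grid$m_max[which.max(grid$beta1)],
                 fits = fits),
            class = "season_scan")
}

#' @export
print.season_scan <- function(x, digits = 4, ...) {
  cat("Peak-risk-month scan (sinusoid seasonal term)\n")
  g <- x$grid
  out <- data.frame(`Peak risk month` = month.name[g$m_max],
                    `Hazard Ratio` = round(g$hr, 3),
                    `Lower 95% CI` = round(g$hr_lower, 3),
                    `Upper 95% CI` = round(g$hr_upper, 3),
                    p = signif(g$p, 3), check.names = FALSE)
  print.data.frame(out, row.names = FALSE)
  cat("Best peak-risk month (max seasonal coefficient): ",
      month.name[x$best_m_max], "\n", sep = "")
  invisible(x)
}

#' Latitude-by-season interaction model
#'
#' Adds a season term (the winter indicator or the sinusoid seasonal
#' risk with a given peak month), latitude in 10-degree steps
#' (`latitude/10`, continuous) and their elementwise product to the
#' adjusted mortality model. The interaction hazard ratio is the
#' multiplicative change in the seasonal effect per 10 degrees of
#' northern latitude. The latitude main effect is retained alongside
#' the interaction (hierarchical principle); drop it via
#' `latitude_main = FALSE`.
#'
#' @inheritParams season_hr
#' @param season `"winter"` for the dichotomous half-year indicator,
#'   `"x1"` for the sinusoid term.
#' @param m_max Peak-risk month used when `season = "x1"`; default 11.
#' @param latitude_main Keep the latitude/10 main effect; default TRUE.
#' @return A `cox_fit` with terms `season`, `lat10` (if retained) and
#'   `season_x_lat10`.
#' @export
latitude_interaction <- function(cases, horizon_months = 36,
                                 season = c("winter", "x1"), m_max = 11,
                                 scheme = stratum_scheme(),
                                 covariates = c("age", "histology", "year",
                                                "sex", "stage"),
                                 references = .default_references,
                                 latitude_main = TRUE, ...) {
  season <- match.arg(season)
  if (anyNA(cases$county_latitude))
    stop("latitude must be present for every case")
  b <- .build_design(cases, horizon_months, covariates, references)
  sv <- if (season == "winter")
    as.numeric(b$cases$month_dx %in% scheme$winter_months)
  else seasonal_risk_term(b$cases$month_dx, m_max)
  lat10 <- b$cases$county_latitude / 10
  d <- design_add_term(b$design, season = sv)
  if (latitude_main) d <- design_add_term(d, lat10 = lat10)
  d <- design_add_term(d, season_x_lat10 = sv * lat10)
  fit_cox(d, ...)
}
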