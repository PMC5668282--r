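# Seeded synthetic registry generator: case listings with the
# statistical structure the seasonality analysis assumes.

#' Synthetic county table
#'
#' The packaged fictional county table: 40 counties spanning
#' 30--48 degrees north with sampling weights whose quartile shares
#' match the registry's latitude strata and whose recomputed quartile
#' cutpoints are exactly 34.19, 38.05 and 41.68 degrees north. Purely
#' synthetic geography (see the file name); it exists to exercise the
#' quartile and north/south logic.
#'
#' @return Data frame with `county_id`, `latitude`, `weight`,
#'   `registry_id`.
#' @export
registry_counties <- function() {
  utils::read.csv(system.file("extdata", "synthetic_counties.csv",
                              package = "hlseason"),
                  stringsAsFactors = FALSE)
}

#' Default covariate marginals
#'
#' Sampling weights for the case-level covariates, matching the
#' published cohort composition: 54.8% male; histology dominated by
#' nodular sclerosis (59.5%); the bimodal-age profile with its large
#' 20--39 component; Ann-Arbor stage II most common (39.4%); and the
#' calendar-period mix of a 1973--2012 registry window.
#'
#' @return Named list of probability vectors (`sex`, `histology`,
#'   `age_group`, `stage`, `year_bin`), each summing to 1.
#' @export
table1_marginals <- function() {
  list(
    sex = c(male = 0.548, female = 0.452),
    histology = c("lymphocyte-rich" = 0.033, "mixed-cellularity" = 0.149,
                  "lymphocyte-depleted" = 0.017, "nodular-sclerosis" = 0.595,
                  "NLPHL" = 0.039, "NOS" = 0.167),
    age_group = c("0-19" = 0.129, "20-29" = 0.238, "30-39" = 0.190,
                  "40-49" = 0.136, "50-59" = 0.101, "60-69" = 0.088,
                  ">=70" = 0.118),
    stage = c(I = 0.213, II = 0.394, III = 0.206, IV = 0.187),
    year_bin = c("<1990" = 0.111, "1990-1999" = 0.218,
                 "2000-2009" = 0.514, ">=2010" = 0.157)
  )
}

.default_covariate_loghr <- function() {
  list(age_per_year = 0.05,       # centered at age 35
       female = -0.15,
       histology = c("lymphocyte-rich" = -0.2, "mixed-cellularity" = 0.2,
                     "lymphocyte-depleted" = 0.6, "nodular-sclerosis" = 0,
                     "NLPHL" = -0.5, "NOS" = 0.1),
       stage = c(I = 0, II = 0.2, III = 0.5, IV = 0.8),
       year_per_year = -0.02)     # centered at year 2000
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic registry. The
#' defaults are the study conditions the package is designed around:
#' a seasonal incidence sinusoid of amplitude 0.077 peaking in March,
#' modulated by calendar month lengths; an extra 0.05 of amplitude
#' per 10 degrees north of 38.05 (reproducing the south/north
#' amplitude contrast); and a seasonal mortality term on the sinusoid
#' risk scale peaking in November.
#'
#' @param n_cases Number of cases to draw.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param incidence_amplitude Relative amplitude `a` of the monthly
#'   diagnosis sinusoid at the reference latitude, in \[0, 1).
#' @param incidence_peak_month Calendar month of peak incidence.
#' @param amplitude_latitude_slope Extra incidence amplitude per 10
#'   degrees north of `reference_latitude` (0 disables the gradient).
#' @param reference_latitude Latitude at which the amplitude equals
#'   `incidence_amplitude`.
#' @param counties County table (`county_id`, `latitude`, `weight`,
#'   `registry_id`); default [registry_counties()].
#' @param marginals Covariate marginals; default [table1_marginals()].
#' @param baseline_hazard Baseline death hazard per month for the
#'   reference case (age 35, male, nodular sclerosis, stage I, year
#'   2000); default 0.0035, giving short-term mortality of the order
#'   seen in registry data.
#' @param covariate_loghr Log hazard ratios for the case covariates
#'   (list with `age_per_year`, `female`, `histology`, `stage`,
#'   `year_per_year`).
#' @param seasonal_loghr Seasonal log hazard ratio `gamma` multiplying
#'   the seasonal term.
#' @param mortality_peak_month Peak-risk month of the mortality
#'   sinusoid; default 11 (November).
#' @param latitude_interaction_loghr Log HR `delta` per 10 degrees
#'   multiplying `seasonal term * latitude/10`; default 0.
#' @param season_form `"cosine"` injects `gamma * x1(month, peak)`;
#'   `"winter"` injects `gamma * 1(September--February)` (the
#'   dichotomous mode), with `delta` interacting analogously.
#' @param followup_horizon_months Administrative censoring horizon.
#' @param censoring_rate Rate (per month) of random loss to follow-up.
#' @param round_months Floor survival to whole months (induces the
#'   heavy event-time ties of month-resolution registry data); set
#'   FALSE for continuous times without ties.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 1000, seed = 1,
                       incidence_amplitude = 0.077,
                       incidence_peak_month = 3,
                       amplitude_latitude_slope = 0.05,
                       reference_latitude = 38.05,
                       counties = registry_counties(),
                       marginals = table1_marginals(),
                       baseline_hazard = 0.0035,
                       covariate_loghr = .default_covariate_loghr(),
                       seasonal_loghr = log(1.06),
                       mortality_peak_month = 11,
                       latitude_interaction_loghr = 0,
                       season_form = c("cosine", "winter"),
                       followup_horizon_months = 480,
                       censoring_rate = 1 / 240,
                       round_months = TRUE) {
  season_form <- match.arg(season_form)
  stopifnot(n_cases >= 1, baseline_hazard > 0, censoring_rate >= 0,
            followup_horizon_months > 0,
            incidence_peak_month %in% 1:12, mortality_peak_month %in% 1:12)
  for (m in marginals) {
    if (any(m < 0) || abs(sum(m) - 1) > 1e-6)
      stop("marginal probabilities must be non-negative and sum to 1")
  }
  a_max <- incidence_amplitude +
    max(0, amplitude_latitude_slope *
          (max(counties$latitude) - reference_latitude) / 10)
  a_min <- incidence_amplitude +
    min(0, amplitude_latitude_slope *
          (min(counties$latitude) - reference_latitude) / 10)
  if (a_max >= 1 || a_min <= -1)
    stop("effective incidence amplitude must stay in (-1, 1) at all latitudes")
  if (any(counties$weight < 0) || abs(sum(counties$weight) - 1) > 1e-6)
    stop("county weights must be non-negative and sum to 1")
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 incidence_amplitude = incidence_amplitude,
                 incidence_peak_month = as.integer(incidence_peak_month),
                 amplitude_latitude_slope = amplitude_latitude_slope,
                 reference_latitude = reference_latitude,
                 counties = counties, marginals = marginals,
                 baseline_hazard = baseline_hazard,
                 covariate_loghr = covariate_loghr,
                 seasonal_loghr = seasonal_loghr,
                 mortality_peak_month = as.integer(mortality_peak_month),
                 latitude_interaction_loghr = latitude_interaction_loghr,
                 season_form = season_form,
                 followup_horizon_months = followup_horizon_months,
                 censoring_rate = censoring_rate,
                 round_months = round_months),
            class = "sim_config")
}

.sample_age <- function(groups, n) {
  lo <- c("0-19" = 0, "20-29" = 20, "30-39" = 30, "40-49" = 40,
          "50-59" = 50, "60-69" = 60, ">=70" = 70)
  hi <- c("0-19" = 19, "20-29" = 29, "30-39" = 39, "40-49" = 49,
          "50-59" = 59, "60-69" = 69, ">=70" = 89)
  lo[groups] + floor(stats::runif(n) * (hi[groups] - lo[groups] + 1))
}

.sample_year <- function(bins, n) {
  lo <- c("<1990" = 1973, "1990-1999" = 1990, "2000-2009" = 2000, ">=2010" = 2010)
  hi <- c("<1990" = 1989, "1990-1999" = 1999, "2000-2009" = 2009, ">=2010" = 2012)
  as.integer(lo[bins] + floor(stats::runif(n) * (hi[bins] - lo[bins] + 1)))
}

#' Simulate a synthetic case registry
#'
#' Draws a full case listing under the configured data-generating
#' process:
#' * month of diagnosis from per-county probabilities
#'   `p_m proportional to (1 + a_eff * cos(2*pi*(m - m0)/12)) * days_m / 30.4375`
#'   with `a_eff = a + slope * (latitude - reference)/10` — a seasonal
#'   sinusoid modulated by calendar month lengths;
#' * covariates from the configured marginals, ages and years uniform
#'   within their sampled bins;
#' * survival from an exponential hazard
#'   `lambda * exp(covariate terms + gamma * s + delta * s * latitude/10)`
#'   where `s` is the seasonal term (`x1` sinusoid or winter
#'   indicator), competing with random censoring and the
#'   administrative horizon;
#' * optional flooring of survival to whole months, inducing the
#'   event-time ties typical of registry data.
#'
#' The RNG state is set from `config$seed` and restored on exit, so
#' identical configs give identical registries.
#'
#' @param config A [sim_config()].
#' @return A case data frame in the canonical [registry_schema()]
#'   layout, with attribute `truth` recording the generative
#'   parameters.
#' @examples
#' cases <- simulate_registry(sim_config(n_cases = 500, seed = 42))
#' head(cases)
#' @export
simulate_registry <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config$seed)
  n <- config$n_cases
  cty <- config$counties
  mg <- config$marginals

  ci <- sample.int(nrow(cty), n, replace = TRUE, prob = cty$weight)
  lat <- cty$latitude[ci]

  # month of diagnosis: per-county sinusoid times month length
  dlen <- month_lengths()
  month_dx <- integer(n)
  a0 <- config$incidence_amplitude
  for (k in sort(unique(ci))) {
    idx <- which(ci == k)
    a_eff <- a0 + config$amplitude_latitude_slope *
      (cty$latitude[k] - config$reference_latitude) / 10
    pm <- (1 + a_eff * cos(2 * pi * (1:12 - config$incidence_peak_month) / 12)) *
      dlen / 30.4375
    month_dx[idx] <- sample.int(12L, length(idx), replace = TRUE, prob = pm)
  }

  sex <- sample(names(mg$sex), n, replace = TRUE, prob = mg$sex)
  histology <- sample(names(mg$histology), n, replace = TRUE, prob = mg$histology)
  stage <- sample(names(mg$stage), n, replace = TRUE, prob = mg$stage)
  age <- .sample_age(sample(names(mg$age_group), n, replace = TRUE,
                            prob = mg$age_group), n)
  year <- .sample_year(sample(names(mg$year_bin), n, replace = TRUE,
                              prob = mg$year_bin), n)

  ch <- config$covariate_loghr
  lp <- ch$age_per_year * (age - 35) +
    ch$female * (sex == "female") +
    unname(ch$histology[histology]) +
    unname(ch$stage[stage]) +
    ch$year_per_year * (year - 2000)
  s <- if (config$season_form == "cosine")
    seasonal_risk_term(month_dx, config$mortality_peak_month)
  else as.numeric(month_dx %in% c(9:12, 1:2))
  lp <- lp + config$seasonal_loghr * s +
    config$latitude_interaction_loghr * s * lat / 10

  rate <- config$baseline_hazard * exp(lp)
  T_death <- stats::rexp(n) / rate
  T_cens <- if (config$censoring_rate > 0)
    stats::rexp(n) / config$censoring_rate else rep(Inf, n)
  t_obs <- pmin(T_death, T_cens, config$followup_horizon_months)
  died <- T_death <= pmin(T_cens, config$followup_horizon_months)
  if (config$round_months) t_obs <- floor(t_obs)

  data.frame(
    case_id = sprintf("case%06d", seq_len(n)),
    month_dx = month_dx,
    year_dx = year,
    age_years = age,
    sex = sex,
    histology = histology,
    stage = stage,
    county_id = cty$county_id[ci],
    county_latitude = lat,
    survival_months = t_obs,
    event = ifelse(died, "death", "censored"),
    flags = "none",
    registry_id = cty$registry_id[ci],
    stringsAsFactors = FALSE
  ) -> cases
  attr(cases, "truth") <- config[setdiff(names(config), c("counties", "marginals"))]
  cases
}
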