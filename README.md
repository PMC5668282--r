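# hlseason

Seasonality analysis of Hodgkin lymphoma (HL) incidence and mortality
from cancer-registry case listings.

HL diagnoses are not spread evenly over the year: monthly counts follow
a sinusoid with a late-winter peak and a late-summer trough, and the
timing of diagnosis also carries prognostic information — a diagnosis
made in the winter half-year is associated with higher short-term
mortality at northern latitudes. `hlseason` implements the full
analysis pipeline for questions of this kind, for epidemiologists
working with registry-style case listings (one row per case: month and
year of diagnosis, demographics, histology, stage, county latitude,
follow-up).

## What it computes

**Incidence seasonality.** Monthly diagnosis counts are adjusted for
month length (February counted as 28.25 days, every month rescaled to
the 30.4375-day average) and standardized so the average month has
incidence 1. A single-component cosinor model is then fit by least
squares:

    y_t = M + A·cos(θ_t − φ) + e_t,   θ_t = 2π(t − 1)/12

with mesor `M`, amplitude `A` (half the peak-to-trough extent) and
acrophase `φ` (angle of the fitted peak, mapped to the nearest calendar
month). Seasonality is tested by the joint 2-df F-test of zero
amplitude; amplitude CIs use the delta method. Group amplitudes (e.g.
northern vs southern counties) are compared in one stacked regression
with group-by-trig interaction terms, and subgroup p-values are
Holm-adjusted.

**Mortality seasonality.** A Cox proportional-hazards model of
short-term mortality (follow-up censored at 36 or 60 months), built
directly on the Efron/Breslow partial likelihood, estimates the hazard
ratio for diagnosis in winter (September–February) versus summer
(March–August), adjusted for age, histological subtype, year of
diagnosis, sex and Ann-Arbor stage. Robustness to the half-year
cutpoints is assessed with the sinusoid seasonal-risk covariate

    x₁ = cos(2π(M − M_max)/12)

(`M` = month of diagnosis) fitted once per candidate peak-risk month
`M_max` = 1..12; the scan selects the `M_max` maximizing the seasonal
coefficient β₁. A latitude interaction model adds latitude in
10-degree steps and its product with the season term.

**Synthetic registries.** `simulate_registry()` generates seeded case
listings with the same structure the analysis assumes — sinusoid
month-of-diagnosis probabilities modulated by month length, realistic
covariate marginals, exponential survival with a log-linear covariate
hazard, a seasonal risk term and a latitude×season interaction, and
administrative plus random censoring — so every stage can be validated
against known ground truth without registry access.

## Worked example

The package ships the published monthly case counts of 41,405 HL cases
as a fixture. Reproducing the incidence analysis:

```r
library(hlseason)
counts <- read.csv(system.file("extdata", "monthly_case_counts.csv",
                               package = "hlseason"))
fit <- cosinor(monthly_incidence(raw_counts = counts$raw_count)$normalized_incidence)
fit
#> Single-component cosinor fit (period 12, n = 12)
#>   mesor     1
#>   amplitude 0.07696  [0.05367, 0.1003]
#>   acrophase 0.9263 rad; peak month 3, trough month 9
#>   zero-amplitude test: F = 20.96, p = 0.00041
```

The seasonal amplitude is 0.077 on the standardized scale: incidence
peaks in March and dips in September, with the fitted March incidence
`100·2A/M` = 15.4% higher than September's
(`peak_trough_percent(fit)`).

Mortality models run on case-level data; here on a synthetic registry
with a known injected winter effect:

```r
cases <- simulate_registry(sim_config(n_cases = 20000, seed = 42,
                                      season_form = "winter",
                                      seasonal_loghr = log(1.3)))
f <- season_hr(cases, horizon_months = 36)
round(summary(f)$table["winter", , drop = FALSE], 4)
#>         coef exp(coef) se(coef)      z lower .95 upper .95 p
#> winter 0.245    1.2777    0.027 9.0842    1.2119     1.347 0
```

The fitted winter-vs-summer hazard ratio 1.28 [1.21, 1.35] recovers the
injected HR of 1.3. `scan_peak_month()` and `latitude_interaction()`
extend this to the sinusoid seasonal-risk scan and the
latitude-dependence of the seasonal effect; `survival_report()`
assembles all of them.

A thin command-line wrapper is included for shell pipelines:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/hlseason.R", package="hlseason"))') \
  simulate --n 1000 --seed 7 --out cases.csv
```

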