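---
title: "Methods: seasonal incidence and mortality models in hlseason"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal incidence and mortality models in hlseason}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlseason)
```

This vignette documents the statistical models in `hlseason`, the
choices behind their defaults, what the synthetic registry generator
does and does not emulate, and the numerical conventions used
throughout.

## 1. Standardized monthly incidence

Monthly diagnosis counts are not directly comparable: months differ in
length by up to 10%. Each month's count is therefore divided by its
length in days and multiplied by the average month length
(30.4375 days). February is counted as 28.25 days — its long-run
average over the leap-year cycle — regardless of the actual mix of
leap years in the data window; over a four-decade registry window the
difference to the exact mix is far below counting noise. The adjusted
counts are then standardized by their own mean, so the average month
has incidence exactly 1 and amplitudes read directly as relative
deviations. Adjusted counts are carried at full precision; integer
rounding happens only in printed tables.

`normalize(adjust(·))` is invariant to rescaling all counts by a
constant, so standardized incidence can be compared across strata of
very different sizes.

## 2. Single-component cosinor

The cosinor model linearizes a cosine of known period (12 months) as

$$y_t = M + \beta_c \cos\theta_t + \beta_s \sin\theta_t + e_t, \qquad
  \theta_t = \frac{2\pi (t-1)}{12},$$

fit by ordinary least squares. Amplitude and acrophase are
$A = \sqrt{\beta_c^2+\beta_s^2}$ and
$\phi = \operatorname{atan2}(\beta_s,\beta_c)$.

Conventions and inference:

* **Phase convention.** $\theta = 0$ corresponds to January
  ($t = 1$). The amplitude is invariant to this choice and the
  acrophase simply shifts with it (a property the test suite checks by
  refitting under a shifted index); the *peak month* is defined
  convention-independently as the month whose angle is closest to the
  acrophase on the circle, with an exact tie broken to the smaller
  month number, and the trough month six months later.
* **Seasonality test.** The joint 2-df F-test of
  $(\beta_c,\beta_s) = (0,0)$ against the mesor-only model — the
  standard zero-amplitude test for a single-component cosinor. Fitting
  the 12 aggregated standardized values leaves 9 residual df.
* **Amplitude CI.** Delta method on $(\beta_c, \beta_s)$ with the OLS
  covariance, the lower bound truncated at 0. On the packaged monthly
  table this puts the peak-vs-trough percentage ($100 \cdot 2A/M$) at
  15.4% with CI [10.7, 20.1]. Bootstrap or population-mean cosinor
  intervals are reasonable alternatives; the delta method was chosen
  because the aggregated series has only 12 points and the amplitude
  is well away from 0, where the delta approximation is accurate.
* **Aggregation level.** The cosinor is fit to the 12 standardized
  monthly values, not to case-level data — only month resolution
  exists in a registry listing. Per-stratum analyses standardize and
  fit within each stratum with the same code path.

Group amplitudes are compared by stacking the two series into one
regression with a group main effect and group × cosine, group × sine
interactions. Each group's amplitude is a norm of its own trig
coefficients; the standard error of the amplitude difference comes
from the delta method using the full 6×6 coefficient covariance, and
the test is a two-sided Wald test. Subgroup zero-amplitude p-values
are adjusted by the step-down Holm procedure (`stats::p.adjust`).

## 3. Cox proportional-hazards core

Short-term mortality is modelled semi-parametrically. Follow-up is
administratively censored at a horizon (36 months by default, 60 for
robustness): longer follow-up dilutes any season-of-diagnosis effect
because patients live through more seasons. The linear predictor
includes the registry risk factors — age at diagnosis (continuous,
years), histological subtype (reference: nodular sclerosis, the
largest group), year of diagnosis (continuous), sex (reference: male)
and Ann-Arbor stage (reference: I) — plus the analysis term of
interest. Reference levels and the continuous coding of age and year
are package choices, not prescribed by the source data; they are
arguments, and year/age could equally enter binned.

The fitter maximizes the partial likelihood directly:

* **Ties.** Survival times in registries are whole months, so tied
  event times are pervasive; the Efron correction is the default.
  Breslow is available, and the two coincide exactly in the absence of
  ties — an identity the tests exploit (the generator can emit
  continuous, tie-free times).
* **Optimization.** Newton–Raphson from $\beta = 0$ with analytic
  score and observed information, step-halving whenever a step would
  reduce the partial log-likelihood, at most 50 iterations.
  Convergence requires the score max-norm to fall below `tol`
  (default 1e-8). With tens of thousands of cases the log-likelihood
  is of order $10^4$–$10^5$, so both the step-acceptance slack
  (1e-10 relative) and the default tolerance are set just above
  double-precision rounding noise at that scale; markedly tighter
  settings make step-halving stall on noise without changing any
  reported digit.
* **Inference.** Standard errors from the inverse observed
  information; per-term Wald z, two-sided p, and 95% CIs
  $\exp(\beta \pm z_{0.975}\,\mathrm{SE})$. Degenerate inputs (no
  events, constant or collinear columns, separation) are refused with
  a diagnosis rather than silently absorbed.

The test suite cross-checks coefficients, standard errors and
log-likelihoods against `survival::coxph` under both tie methods, and
against direct grid maximization of the enumerated partial likelihood
on a small no-ties dataset.

## 4. Seasonal terms, the peak-month scan, and latitude

The **dichotomous season** covariate assigns September–February to the
winter half-year and March–August to summer (meteorological seasons:
winter = autumn + winter months). The **sinusoid seasonal-risk term**
replaces it by $x_1 = \cos(2\pi (M - M_{\max})/12)$: +1 in the
hypothesized peak-risk month, −1 six months away, 0 at the quarter
points. The scan refits the model for every $M_{\max} \in \{1..12\}$
and selects the month maximizing $\beta_1$. Because shifting
$M_{\max}$ by six months flips the sign of the covariate exactly,
$\beta_1(m) = -\beta_1(m+6)$ and $\mathrm{HR}(m)\mathrm{HR}(m+6) = 1$
identically — a structural invariant the tests assert to 1e-10. The
scan is month-resolved because diagnosis dates are; a finer grid can
be supplied via `m_grid`.

The **latitude interaction** model adds the season term, latitude in
10-degree steps (latitude/10, continuous) and their product. The
latitude main effect is retained by default (hierarchical principle) —
whether the original analysis did so is unknowable from the published
tables, so it is a documented, toggleable choice (`latitude_main`).
The interaction coefficient is invariant to shifting all latitudes by
a constant; only the season main effect reparameterizes, which the
tests verify.

When data are simulated with both a seasonal effect $\gamma$ and an
uncentered latitude interaction $\delta$ (hazard term
$\gamma x_1 + \delta x_1 \cdot \mathrm{lat}/10$), the scan's marginal
$\beta_1$ estimates $\gamma + \delta\,\mathrm{E}[\mathrm{lat}/10]$,
not $\gamma$; recovering the separate components requires the
interaction model, which is then correctly specified. The recovery
tests do exactly that.

## 5. The synthetic registry generator

`simulate_registry()` draws, per case: a county (weighted table), a
diagnosis month from
$p_m \propto (1 + a_\mathrm{eff}\cos(2\pi(m-m_0)/12)) \cdot d_m/30.4375$
with $a_\mathrm{eff} = a + s\,(\mathrm{lat}-\mathrm{ref})/10$,
covariates from configurable marginals, and an exponential survival
time with rate
$\lambda \exp(\mathrm{covariates} + \gamma s + \delta s\,\mathrm{lat}/10)$,
censored by an administrative horizon and random loss to follow-up,
then floored to whole months.

Defaults are fixed once as the conditions the package is designed
around:

* incidence amplitude $a = 0.077$ peaking in March, with an extra
  0.05 amplitude per 10° north of 38.05°N — reproducing the published
  south/north amplitude contrast of roughly 0.055 vs 0.102;
* mortality sinusoid peaking in November with
  $\gamma = \ln 1.06$ by default ($\delta = 0$; nonzero $\delta$ in
  the uncentered form quickly dominates the seasonal effect at
  US latitudes, so it is switched on only in targeted experiments);
* baseline hazard 0.0035/month for the reference case (male, age 35,
  nodular sclerosis, stage I, year 2000) with log-linear covariate
  effects of plausible sign and size (age +0.05/yr, stage II/III/IV
  +0.2/+0.5/+0.8, improving calendar-year trend −0.02/yr), giving
  3-year mortality in the low twenties of percent — the order observed
  in long-window registry cohorts;
* a packaged, explicitly synthetic 40-county table spanning
  30–48°N whose recomputed quartile cutpoints are exactly
  34.19/38.05/41.68°N.

What the generator does **not** emulate: real county geography or
population sizes, secular changes in registry coverage, EBV status,
treatment, stage migration, correlation between covariates (all
marginals are independent), non-exponential baseline hazards, or
informative censoring. Passing recovery tests therefore show that the
estimators invert the assumed data-generating process at registry
scale — not that the substantive findings would replicate in data
violating those assumptions. Flooring survival to months additionally
grays the likelihood slightly: recovered seasonal coefficients are
attenuated by a few percent relative to the continuous-time truth,
which the recovery tests' tolerances accommodate.

## 6. Stratification and exclusion conventions

* Latitude quartiles are computed over **distinct counties**, not
  cases; cases inherit their county's quartile. Cutpoints sit **at**
  the latitude of the first county of each upper group, giving
  half-open, lower-inclusive intervals (e.g. quartile 2 is
  ≥34.19°N and <38.05°N). Placing cutpoints midway between adjacent
  counties is an equally defensible convention; the published
  cutpoints are treated as constants to reproduce, not a recomputation
  target, since the real county list is not shipped.
* The north/south split reuses the middle cutpoint (38.05°N),
  lower-inclusive for north.
* Age groups 0–19, 20–29, …, ≥70; year bins <1990, 1990s, 2000s,
  ≥2010; both are stratification-time bins over continuous stored
  values, so other groupings remain possible.
* Exclusion rules are applied sequentially with per-rule accounting
  (removed, remaining); the two low-count registries are removed as a
  single parameterized rule because they are excluded for the same
  reason. Missing values are the empty string or `NA` in the CSV
  dialect; unparseable fields are reported and set missing, never
  silently dropped — the cascade decides their fate explicitly.

## 7. Problem sizes in the shipped checks

The validation suite aggregates the packaged 12-month table (exact,
instantaneous) and simulates cohorts of 2,000–50,000 cases for
property and recovery checks, with 40,000–50,000 used for the
parameter-recovery runs where Monte-Carlo error must sit comfortably
inside the recovery bands. These sizes mirror the scale of the cohort
the method targets (~41,000 cases) while keeping the whole suite in
the tens of seconds on one CPU.

## 8. Known limitations

* Single-component cosinor only; no higher harmonics (month-resolution
  aggregated data give them little support).
* The Cox core has no time-varying covariates, stratified baselines,
  frailty terms, or proportionality diagnostics; it is a focused
  engine for the seasonal contrasts.
* Amplitude CIs on 12 aggregated points lean on large-count normality
  of the monthly totals; for small strata (hundreds of cases) they are
  approximate and the Holm-adjusted tests are conservative.
* The peak-month scan selects the maximizing month without a
  selection-adjusted p-value; the six-month antisymmetry means the
  scan's p-values are those of the individual fits.
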