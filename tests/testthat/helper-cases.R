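# Small in-code fixtures shared across test files.

# Minimal hand-built case table (canonical schema).
toy_cases <- function(n = 10,
                      month_dx = rep(1:12, length.out = n),
                      age_years = rep(30, n),
                      sex = rep("male", n),
                      histology = rep("nodular-sclerosis", n),
                      stage = rep("II", n),
                      county_latitude = rep(40, n),
                      survival_months = rep(24, n),
                      event = rep("censored", n),
                      flags = rep("none", n),
                      registry_id = rep("R01", n),
                      year_dx = rep(2005, n)) {
  data.frame(case_id = sprintf("t%03d", seq_len(n)), month_dx = month_dx,
             year_dx = year_dx, age_years = age_years, sex = sex,
             histology = histology, stage = stage,
             county_id = rep("C01", n), county_latitude = county_latitude,
             survival_months = survival_months, event = event, flags = flags,
             registry_id = registry_id, stringsAsFactors = FALSE)
}

# Published raw monthly counts (packaged fixture).
published_counts <- function() {
  read.csv(system.file("extdata", "monthly_case_counts.csv",
                       package = "hlseason"))$raw_count
}

# Direct (no-ties) Cox partial log-likelihood, enumerated from its
# definition; independent oracle for the Newton-Raphson fitter.
enumerated_partial_loglik <- function(beta, time, status, x) {
  eta <- beta * x
  sum(vapply(which(status == 1), function(i) {
    eta[i] - log(sum(exp(eta[time >= time[i]])))
  }, numeric(1)))
}

# Single-covariate exponential survival data with administrative
# censoring; continuous times (no ties).
sim_surv1 <- function(n, beta, base = 0.02, admin = 60, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n) / (base * exp(beta * x))
  list(time = pmin(tt, admin), status = as.integer(tt <= admin), x = x)
}

design_from <- function(time, status, ...) {
  X <- cbind(...)
  structure(list(time = time, status = as.integer(status), X = X,
                 n = length(time), n_events = sum(status),
                 references = list()),
            class = "survival_design")
}
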