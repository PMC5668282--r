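# Cox proportional-hazards core: partial likelihood with Efron or
# Breslow tie handling, Newton-Raphson with step-halving.

#' Build follow-up time and event columns under an analysis horizon
#'
#' Censors follow-up administratively at `horizon_months`: time is
#' `min(survival_months, horizon)` and a death counts as an event only
#' if it occurred at or before the horizon. Horizons of 36 and 60
#' months focus the model on short-term mortality.
#'
#' @param cases Case data frame with `survival_months` and `event`
#'   (`"death"`/`"censored"`).
#' @param horizon_months Positive horizon; typically 36 or 60.
#' @return `cases` with numeric `time` and 0/1 `status` columns added.
#' @export
make_survival <- function(cases, horizon_months = 36) {
  stopifnot(horizon_months > 0)
  if (any(is.na(cases$survival_months)) || any(cases$survival_months < 0))
    stop("survival_months must be present and non-negative")
  death <- cases$event == "death"
  cases$time <- pmin(cases$survival_months, horizon_months)
  cases$status <- as.integer(death & cases$survival_months <= horizon_months)
  cases
}

.default_references <- list(sex = "male", histology = "nodular-sclerosis",
                            stage = "I")
.factor_levels <- function(col) {
  switch(col, sex = .sex_levels, histology = .histology_levels,
         stage = .stage_levels, stop("no canonical levels for ", col))
}

#' Encode the covariate design for the mortality models
#'
#' Builds the named design matrix for [fit_cox()] from a case data
#' frame: continuous terms are passed through (age in years, year of
#' diagnosis as a calendar year), factors become treatment-coded
#' dummies against a stated reference level (k-1 columns for a
#' k-level factor) in a deterministic column order. A level found in
#' the data but absent from the canonical level set is an error
#' naming the level.
#'
#' @param cases Case data frame, already passed through
#'   [make_survival()].
#' @param covariates Character vector of model terms drawn from
#'   `"age"`, `"histology"`, `"year"`, `"sex"`, `"stage"` (the
#'   registry risk factors); default all five.
#' @param references Named list of reference levels for the factor
#'   terms; defaults: sex male, histology nodular-sclerosis, stage I.
#' @return A `survival_design` list: `time`, `status`, `X` (numeric
#'   matrix with named columns), `n`, `n_events`, `references`.
#' @export
encode_covariates <- function(cases,
                              covariates = c("age", "histology", "year",
                                             "sex", "stage"),
                              references = .default_references) {
  if (is.null(cases$time) || is.null(cases$status))
    stop("cases lack time/status; run make_survival() first")
  refs <- utils::modifyList(.default_references, as.list(references))
  cols <- list()
  for (cv in covariates) {
    if (cv == "age") {
      cols[["age_years"]] <- as.numeric(cases$age_years)
    } else if (cv == "year") {
      cols[["year_dx"]] <- as.numeric(cases$year_dx)
    } else if (cv %in% c("sex", "histology", "stage")) {
      levs <- .factor_levels(cv)
      vals <- cases[[cv]]
      bad <- setdiff(unique(vals[!is.na(vals)]), levs)
      if (length(bad))
        stop("unknown ", cv, " level(s): ", paste(bad, collapse = ", "))
      ref <- refs[[cv]]
      if (!ref %in% levs) stop("reference level ", ref, " not a ", cv, " level")
      for (lv in setdiff(levs, ref))
        cols[[paste0(cv, "=", lv)]] <- as.numeric(vals == lv)
    } else {
      stop("unknown covariate term: ", cv)
    }
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(cases), ncol = 0)
  if (anyNA(X)) stop("covariates contain missing values; exclude such cases first")
  structure(list(time = cases$time, status = cases$status, X = X,
                 n = nrow(cases), n_events = sum(cases$status),
                 references = refs),
            class = "survival_design")
}

#' Append an analysis term to a survival design
#'
#' Adds a named numeric column (e.g. a winter indicator, the sinusoid
#' seasonal-risk term, latitude in 10-degree steps, or an elementwise
#' product for an interaction) to the design matrix.
#'
#' @param design A `survival_design`.
#' @param ... Named numeric vectors of length `design$n`.
#' @return The augmented design.
#' @export
design_add_term <- function(design, ...) {
  stopifnot(inherits(design, "survival_design"))
  terms <- list(...)
  for (nm in names(terms)) {
    v <- as.numeric(terms[[nm]])
    stopifnot(length(v) == design$n)
    design$X <- cbind(design$X, v)
    colnames(design$X)[ncol(design$X)] <- nm
  }
  design
}

# Partial log-likelihood, score and observed information in one pass.
# Data must be sorted by increasing time; deaths tied at a time are
# handled by the Efron weights l/d (Breslow: all weights 0).
.cox_derivs <- function(beta, time, status, X, ties) {
  n <- length(time); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                  # guard exp overflow; cancels in ratios
  r <- exp(eta)
  rX <- X * r

  ut <- unique(time)                     # increasing
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  # walk times from largest to smallest, growing the risk set
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  hi <- n
  for (k in rev(seq_along(ut))) {
    lo <- hi
    while (lo > 1L && time[lo - 1L] == ut[k]) lo <- lo - 1L
    idx <- lo:hi
    S0 <- S0 + sum(r[idx])
    S1 <- S1 + colSums(rX[idx, , drop = FALSE])
    S2 <- S2 + crossprod(X[idx, , drop = FALSE], rX[idx, , drop = FALSE])
    d_idx <- idx[status[idx] == 1L]
    d <- length(d_idx)
    if (d > 0L) {
      w <- if (ties == "efron") (seq_len(d) - 1) / d else numeric(d)
      s0d <- sum(r[d_idx])
      s1d <- colSums(rX[d_idx, , drop = FALSE])
      s2d <- crossprod(X[d_idx, , drop = FALSE], rX[d_idx, , drop = FALSE])
      den <- S0 - w * s0d
      a <- 1 / den; b <- w / den
      sa <- sum(a); sb <- sum(b)
      ll <- ll + sum(eta[d_idx]) - sum(log(den))
      grad <- grad + colSums(X[d_idx, , drop = FALSE]) - (sa * S1 - sb * s1d)
      # E[x] and E[xx'] under each weighted risk distribution
      saa <- sum(a^2); sab <- sum(a * b); sbb <- sum(b^2)
      ZZ <- saa * tcrossprod(S1) -
        sab * (tcrossprod(S1, s1d) + tcrossprod(s1d, S1)) +
        sbb * tcrossprod(s1d)
      info <- info + (sa * S2 - sb * s2d) - ZZ
    }
    hi <- lo - 1L
    if (hi < 1L) break
  }
  list(loglik = ll, gradient = grad, info = info)
}

#' Fit a Cox proportional-hazards model by partial likelihood
#'
#' Maximizes the Cox partial likelihood over the design's covariates
#' by Newton-Raphson from beta = 0, with step-halving whenever a step
#' would decrease the partial log-likelihood. Tied event times —
#' pervasive here because survival is recorded in whole months — use
#' the Efron correction by default; Breslow is available and the two
#' coincide exactly when no times are tied. Standard errors come from
#' the inverse observed information; Wald 95% CIs and two-sided
#' p-values are reported per term.
#'
#' @param design A `survival_design` from [encode_covariates()]
#'   (optionally extended by [design_add_term()]).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the max-norm of the score;
#'   default 1e-8 (with tens of thousands of cases the score is a sum
#'   of that many O(1) terms, so much tighter thresholds sit below
#'   double-precision rounding noise).
#' @param max_iter Maximum Newton iterations; default 50.
#' @param init Optional starting coefficients; default all zero.
#' @return An object of class `cox_fit`: `coefficients`, `se`,
#'   `vcov`, `hr` with `hr_ci`, `p`, `loglik` (c(null, final)),
#'   `iter`, `converged`, `ties`, `n`, `n_events`.
#' @export
fit_cox <- function(design, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 50L, init = NULL) {
  stopifnot(inherits(design, "survival_design"))
  ties <- match.arg(ties)
  X <- design$X
  if (ncol(X) < 1L) stop("design has no covariate columns")
  if (design$n_events < 1L) stop("no events in the data; cannot fit")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (collinear columns)")

  ord <- order(design$time)
  time <- design$time[ord]; status <- design$status[ord]
  Xs <- X[ord, , drop = FALSE]
  p <- ncol(X)
  beta <- if (is.null(init)) numeric(p) else as.numeric(init)

  cur <- .cox_derivs(beta, time, status, Xs, ties)
  loglik0 <- if (all(beta == 0)) cur$loglik else
    .cox_derivs(numeric(p), time, status, Xs, ties)$loglik
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    if (max(abs(cur$gradient)) < tol) { converged <- TRUE; break }
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$gradient),
                     error = function(e) stop("singular information matrix; ",
                                              "possible separation or collinearity"))
    # accept a step unless it decreases the log-likelihood beyond
    # rounding noise (the likelihood is a sum of |D| O(1) terms)
    ll_slack <- 1e-10 * (abs(cur$loglik) + 1)
    new <- NULL
    for (h in 0:20) {
      cand <- beta + step / 2^h
      new <- .cox_derivs(cand, time, status, Xs, ties)
      if (is.finite(new$loglik) && new$loglik >= cur$loglik - ll_slack) {
        beta <- cand; break
      }
      new <- NULL
    }
    if (is.null(new)) break                 # step-halving exhausted
    cur <- new
  }
  if (!converged && max(abs(cur$gradient)) < tol) converged <- TRUE
  if (!converged)
    warning("Newton-Raphson did not converge in ", iter,
            " iterations (max |score| = ", format(max(abs(cur$gradient))), ")")

  V <- solve(cur$info)
  se <- sqrt(diag(V))
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  zc <- stats::qnorm(0.975)
  z <- beta / se
  structure(list(
    coefficients = beta, se = stats::setNames(se, colnames(X)), vcov = V,
    hr = exp(beta),
    hr_ci = cbind(lower = exp(beta - zc * se), upper = exp(beta + zc * se)),
    z = z, p = 2 * stats::pnorm(-abs(z)),
    loglik = c(null = loglik0, final = cur$loglik),
    score_norm = max(abs(cur$gradient)),
    iter = iter, converged = converged, ties = ties,
    n = design$n, n_events = design$n_events,
    call = match.call()
  ), class = "cox_fit")
}

#' Evaluate the Cox partial log-likelihood at given coefficients
#'
#' Exposes the partial log-likelihood itself (no maximization), e.g.
#' for profiling or for cross-checking the maximizer against a direct
#' grid search.
#'
#' @param design A `survival_design`.
#' @param beta Coefficient vector.
#' @inheritParams fit_cox
#' @return The partial log-likelihood value.
#' @export
cox_loglik <- function(design, beta, ties = c("efron", "breslow")) {
  stopifnot(inherits(design, "survival_design"))
  ties <- match.arg(ties)
  ord <- order(design$time)
  .cox_derivs(as.numeric(beta), design$time[ord], design$status[ord],
              design$X[ord, , drop = FALSE], ties)$loglik
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$vcov

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik[["final"]], df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  zc <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zc * object$se,
              object$coefficients + zc * object$se)
  colnames(ci) <- paste0(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.cox_fit <- function(object, ...) {
  tab <- cbind(coef = object$coefficients, `exp(coef)` = object$hr,
               `se(coef)` = object$se, z = object$z,
               `lower .95` = object$hr_ci[, "lower"],
               `upper .95` = object$hr_ci[, "upper"], p = object$p)
  structure(list(fit = object, table = tab), class = "summary.cox_fit")
}

#' @export
print.summary.cox_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Cox proportional-hazards fit (", f$ties, " ties), n = ", f$n,
      ", events = ", f$n_events, "\n", sep = "")
  stats::printCoefmat(x$table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("Partial log-likelihood: ", format(f$loglik[["final"]], digits = 8),
      " (null ", format(f$loglik[["null"]], digits = 8), "); ",
      f$iter, " iterations, ",
      if (f$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  print(summary(x), digits = digits, ...)
  invisible(x)
}
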