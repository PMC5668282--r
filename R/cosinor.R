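# Single-component cosinor rhythmometry.

.month_angle <- function(t, period) 2 * pi * (t - 1) / period

#' Fit a single-component cosinor model
#'
#' Least-squares fit of
#' \deqn{y_t = M + \beta_c \cos\theta_t + \beta_s \sin\theta_t + e_t,
#'       \quad \theta_t = 2\pi (t - 1)/\mathrm{period},}
#' the linearization of \eqn{M + A\cos(\theta_t - \phi)} with mesor
#' \eqn{M} (rhythm-adjusted mean), amplitude
#' \eqn{A = \sqrt{\beta_c^2 + \beta_s^2}} (half the peak-to-trough
#' extent) and acrophase \eqn{\phi = \mathrm{atan2}(\beta_s, \beta_c)}
#' (angle of the fitted maximum). With `t = 1` for January and period
#' 12, \eqn{\theta = 0} is the January angle; the amplitude is
#' invariant to this phase convention and only the acrophase shifts
#' with it.
#'
#' Inference: the overall seasonality test is the joint 2-df F-test of
#' \eqn{(\beta_c, \beta_s) = (0, 0)} against the mesor-only model; the
#' amplitude standard error and 95% CI come from the delta method on
#' \eqn{(\beta_c, \beta_s)} with the OLS coefficient covariance, the
#' lower bound truncated at 0.
#'
#' @param y Periodic observations (e.g. the 12 standardized monthly
#'   incidence values, or any longer periodic series).
#' @param t Time index of each observation (month number for monthly
#'   data); default `seq_along(y)`.
#' @param period Period in the units of `t`; default 12.
#' @return An object of class `cosinor` with components
#'   `coefficients` (mesor, beta_cos, beta_sin), `amplitude`,
#'   `acrophase` (radians in \[0, 2pi)), `peak_month`, `trough_month`,
#'   `amplitude_se`, `amplitude_ci`, `seasonality_p`, `vcov`, `sigma2`,
#'   `df_residual`, `fitted.values`, `residuals`, `n`, `period`.
#' @examples
#' counts <- read.csv(system.file("extdata", "monthly_case_counts.csv",
#'                                package = "hlseason"))
#' inc <- monthly_incidence(raw_counts = counts$raw_count)
#' fit <- cosinor(inc$normalized_incidence)
#' summary(fit)
#' @export
cosinor <- function(y, t = seq_along(y), period = 12) {
  stopifnot(length(y) == length(t), period > 0)
  if (length(unique(t %% period)) < 4L)
    stop("need observations at >= 4 distinct phases to fit 3 parameters")
  if (length(y) < 4L)
    stop("need at least 4 observations")
  theta <- .month_angle(t, period)
  X <- cbind(mesor = 1, beta_cos = cos(theta), beta_sin = sin(theta))
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  df <- length(y) - 3L
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  V <- sigma2 * XtXinv
  dimnames(V) <- list(colnames(X), colnames(X))

  A <- sqrt(beta[2]^2 + beta[3]^2)
  phi <- atan2(beta[3], beta[2]) %% (2 * pi)
  # delta method: dA/dbeta = (beta_c, beta_s)/A
  a_se <- if (A > 0) {
    g <- c(0, beta[2], beta[3]) / A
    sqrt(drop(t(g) %*% V %*% g))
  } else NA_real_
  zc <- stats::qnorm(0.975)
  a_ci <- c(max(0, A - zc * a_se), A + zc * a_se)

  # joint zero-amplitude F-test vs the mesor-only model
  rss0 <- sum((y - mean(y))^2)
  Fstat <- ((rss0 - rss) / 2) / sigma2
  p_season <- stats::pf(Fstat, 2, df, lower.tail = FALSE)

  out <- structure(list(
    coefficients = beta,
    amplitude = unname(A),
    acrophase = unname(phi),
    amplitude_se = unname(a_se),
    amplitude_ci = unname(a_ci),
    seasonality_F = unname(Fstat),
    seasonality_p = unname(p_season),
    vcov = V,
    sigma2 = sigma2,
    df_residual = df,
    fitted.values = drop(X %*% beta),
    residuals = unname(fit$residuals),
    y = y, t = t, n = length(y), period = period,
    call = match.call()
  ), class = "cosinor")
  out$peak_month <- peak_month(out)
  out$trough_month <- (out$peak_month - 1L + period %/% 2L) %% period + 1L
  out
}

#' Month nearest the fitted peak
#'
#' Maps the acrophase to the calendar month whose angle is closest on
#' the circle; a tie exactly between two months is broken to the
#' smaller month number. The trough month sits half a period later.
#'
#' @param fit A [cosinor()] fit.
#' @return Integer month in 1..period.
#' @export
peak_month <- function(fit) {
  stopifnot(inherits(fit, "cosinor"))
  p <- fit$period
  ang <- .month_angle(seq_len(p), p)
  d <- abs(((ang - fit$acrophase + pi) %% (2 * pi)) - pi)
  as.integer(which.min(round(d, 9)))
}

#' Fitted peak-minus-trough difference as a percentage of the mesor
#'
#' The fitted curve ranges from mesor - A to mesor + A, so the peak
#' exceeds the trough by `100 * 2A / mesor` percent of the mesor. On
#' standardized incidence (mesor 1) this is the "peak month incidence
#' is x% higher than the trough month" figure. A 95% CI is attached
#' by the delta method on (mesor, beta_c, beta_s).
#'
#' @param fit A [cosinor()] fit with positive mesor.
#' @return Percentage (single number) with attribute `ci`.
#' @export
peak_trough_percent <- function(fit) {
  stopifnot(inherits(fit, "cosinor"))
  M <- fit$coefficients[1]
  if (!is.finite(M) || M <= 0) stop("mesor must be positive")
  A <- fit$amplitude
  pct <- 100 * 2 * A / M
  g <- 100 * c(-2 * A / M^2, 2 * fit$coefficients[2] / (A * M),
               2 * fit$coefficients[3] / (A * M))
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  zc <- stats::qnorm(0.975)
  structure(unname(pct), ci = unname(pct + c(-1, 1) * zc * se))
}

#' @export
coef.cosinor <- function(object, ...) object$coefficients

#' @export
vcov.cosinor <- function(object, ...) object$vcov

#' @export
residuals.cosinor <- function(object, ...) object$residuals

#' @export
fitted.cosinor <- function(object, ...) object$fitted.values

#' @export
predict.cosinor <- function(object, t = object$t, ...) {
  theta <- .month_angle(t, object$period)
  drop(cbind(1, cos(theta), sin(theta)) %*% object$coefficients)
}

#' @export
print.cosinor <- function(x, digits = 4, ...) {
  cat("Single-component cosinor fit (period ", x$period, ", n = ", x$n, ")\n",
      sep = "")
  cat("  mesor     ", format(x$coefficients[1], digits = digits), "\n",
      "  amplitude ", format(x$amplitude, digits = digits),
      "  [", format(x$amplitude_ci[1], digits = digits), ", ",
      format(x$amplitude_ci[2], digits = digits), "]\n",
      "  acrophase ", format(x$acrophase, digits = digits),
      " rad; peak month ", x$peak_month,
      ", trough month ", x$trough_month, "\n",
      "  zero-amplitude test: F = ", format(x$seasonality_F, digits = digits),
      ", p = ", format.pval(x$seasonality_p, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cosinor <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tval <- object$coefficients / se
  ptab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                `t value` = tval,
                `Pr(>|t|)` = 2 * stats::pt(-abs(tval), object$df_residual))
  structure(list(fit = object, coef_table = ptab,
                 peak_trough_percent = peak_trough_percent(object)),
            class = "summary.cosinor")
}

#' @export
print.summary.cosinor <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coef_table, digits = digits)
  pt <- x$peak_trough_percent
  cat("\nPeak vs trough: ", format(pt, digits = digits), "% [",
      format(attr(pt, "ci")[1], digits = digits), ", ",
      format(attr(pt, "ci")[2], digits = digits), "] of the mesor\n", sep = "")
  invisible(x)
}

#' @export
plot.cosinor <- function(x, xlab = "Month", ylab = "Incidence", ...) {
  tt <- seq(min(x$t), max(x$t), length.out = 200)
  graphics::plot(x$t, x$y, xlab = xlab, ylab = ylab, ...)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(h = x$coefficients[1], lty = 2)
  invisible(x)
}

#' Compare cosinor amplitudes between two groups
#'
#' Stacks the two periodic series and fits one regression with a
#' group main effect and group-by-cosine, group-by-sine interactions,
#' so each group gets its own trig coefficients. Per-group amplitudes
#' are derived from those coefficients; the standard error of the
#' amplitude difference comes from the delta method on all four trig
#' terms with the full OLS covariance, and the test is a two-sided
#' Wald test of zero difference.
#'
#' @param y_a,y_b Periodic series for the two groups (e.g.
#'   standardized monthly incidence south and north), same length and
#'   time index.
#' @param t Time index; default `seq_along(y_a)`.
#' @param period Period; default 12.
#' @return An `amplitude_comparison` list: `amplitude_a`,
#'   `amplitude_b`, `difference` (b minus a), `difference_se`,
#'   `difference_ci`, `p_value`, plus the stacked-model coefficients.
#' @export
compare_amplitudes <- function(y_a, y_b, t = seq_along(y_a), period = 12) {
  stopifnot(length(y_a) == length(t), length(y_b) == length(t))
  theta <- .month_angle(t, period)
  g <- rep(c(0, 1), each = length(t))
  cth <- rep(cos(theta), 2); sth <- rep(sin(theta), 2)
  y <- c(y_a, y_b)
  X <- cbind(mesor = 1, group = g, beta_cos = cth, beta_sin = sth,
             g_cos = g * cth, g_sin = g * sth)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  df <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  V <- sigma2 * chol2inv(chol(crossprod(X)))

  ca <- beta["beta_cos"]; sa <- beta["beta_sin"]
  cb <- ca + beta["g_cos"]; sb <- sa + beta["g_sin"]
  A_a <- sqrt(ca^2 + sa^2); A_b <- sqrt(cb^2 + sb^2)
  if (A_a < 1e-12 && A_b < 1e-12)
    stop("both series are constant over the period; amplitudes undefined")
  # d(A_b - A_a)/d(beta) over (mesor, group, beta_cos, beta_sin, g_cos, g_sin)
  grad <- c(0, 0,
            cb / A_b - ca / A_a,
            sb / A_b - sa / A_a,
            cb / A_b,
            sb / A_b)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  diff <- A_b - A_a
  z <- diff / se
  zc <- stats::qnorm(0.975)
  structure(list(
    amplitude_a = unname(A_a), amplitude_b = unname(A_b),
    difference = unname(diff), difference_se = unname(se),
    difference_ci = unname(diff + c(-1, 1) * zc * se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    coefficients = beta, vcov = V, df_residual = df
  ), class = "amplitude_comparison")
}

#' @export
print.amplitude_comparison <- function(x, digits = 4, ...) {
  cat("Cosinor amplitude comparison\n",
      "  group A amplitude ", format(x$amplitude_a, digits = digits), "\n",
      "  group B amplitude ", format(x$amplitude_b, digits = digits), "\n",
      "  difference (B - A) ", format(x$difference, digits = digits),
      " [", format(x$difference_ci[1], digits = digits), ", ",
      format(x$difference_ci[2], digits = digits), "], p = ",
      format.pval(x$p_value, digits = digits), "\n", sep = "")
  invisible(x)
}
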