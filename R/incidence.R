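# Monthly aggregation, month-length adjustment, standardization, Holm.

#' Calendar month lengths with averaged February
#'
#' Month lengths in days used for the length adjustment. February is
#' counted as 28.25 days (the long-run average over the leap-year
#' cycle), all other months at their calendar length; the mean over
#' the 12 months is 30.4375 days.
#'
#' @param feb_days Length of February; default 28.25.
#' @return Numeric vector of 12 month lengths.
#' @export
month_lengths <- function(feb_days = 28.25) {
  c(31, feb_days, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
}

#' Tally cases by month of diagnosis
#'
#' @param cases Case data frame with a `month_dx` column in 1--12.
#' @return Integer vector of length 12 (January first); sums to the
#'   number of cases with a known month.
#' @export
monthly_counts <- function(cases) {
  tabulate(cases$month_dx[!is.na(cases$month_dx)], nbins = 12L)
}

#' Adjust monthly counts for month length
#'
#' Divides each month's count by that month's length in days and
#' multiplies by the average month length, so months are compared on
#' an equal-duration footing: `adjusted = raw / length * target`.
#'
#' @param raw_counts Numeric vector of 12 monthly counts.
#' @param lengths Month lengths in days; default [month_lengths()].
#' @param target_length Average month length; default 30.4375.
#' @return Numeric vector of adjusted counts (full precision; round
#'   only for display).
#' @export
adjust_month_length <- function(raw_counts, lengths = month_lengths(),
                                target_length = 30.4375) {
  stopifnot(length(raw_counts) == length(lengths))
  if (any(lengths <= 0) || target_length <= 0)
    stop("month lengths must be positive")
  if (any(raw_counts < 0)) stop("counts must be non-negative")
  raw_counts / lengths * target_length
}

#' Standardize adjusted counts to mean incidence 1
#'
#' Divides each month's adjusted count by the mean over all months,
#' so the average month has incidence exactly 1.
#'
#' @param adjusted_counts Numeric vector of adjusted counts, not all
#'   zero.
#' @return Numeric vector with mean 1.
#' @export
normalize_incidence <- function(adjusted_counts) {
  m <- mean(adjusted_counts)
  if (!is.finite(m) || m <= 0)
    stop("cannot standardize: mean adjusted count is not positive")
  adjusted_counts / m
}

#' Monthly incidence table
#'
#' Builds the per-month incidence table: raw counts, month lengths,
#' length-adjusted counts and standardized (mean 1) incidence.
#' Supply either a case data frame or a vector of 12 raw counts.
#'
#' @param cases Case data frame with `month_dx` (ignored when
#'   `raw_counts` is given).
#' @param raw_counts Optional numeric vector of 12 monthly counts,
#'   January first.
#' @param feb_days February length in days; default 28.25.
#' @return A `monthly_incidence` data frame with columns `month`,
#'   `month_name`, `raw_count`, `month_length_days`, `adjusted_count`,
#'   `normalized_incidence`.
#' @examples
#' counts <- read.csv(system.file("extdata", "monthly_case_counts.csv",
#'                                package = "hlseason"))
#' monthly_incidence(raw_counts = counts$raw_count)
#' @export
monthly_incidence <- function(cases = NULL, raw_counts = NULL,
                              feb_days = 28.25) {
  if (is.null(raw_counts)) {
    if (is.null(cases)) stop("supply cases or raw_counts")
    raw_counts <- monthly_counts(cases)
  }
  stopifnot(length(raw_counts) == 12L)
  len <- month_lengths(feb_days)
  adj <- adjust_month_length(raw_counts, len)
  out <- data.frame(
    month = 1:12,
    month_name = month.name,
    raw_count = raw_counts,
    month_length_days = len,
    adjusted_count = adj,
    normalized_incidence = normalize_incidence(adj),
    stringsAsFactors = FALSE
  )
  class(out) <- c("monthly_incidence", "data.frame")
  out
}

#' @export
print.monthly_incidence <- function(x, digits = 3, ...) {
  y <- data.frame(Month = x$month_name,
                  `Case count` = x$raw_count,
                  `Adjusted count` = round(x$adjusted_count),
                  `Normalized incidence` = round(x$normalized_incidence, digits),
                  check.names = FALSE)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down Holm (Bonferroni-Holm) adjustment with monotonicity
#' enforcement, capped at 1. Adjusted p-values are elementwise at
#' least as large as the raw ones.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}
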