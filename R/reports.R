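# Report assembly: the monthly-incidence table with its cosinor fit,
# per-stratum forest tables, and the seasonal-mortality summaries.

#' Incidence seasonality report
#'
#' Assembles the per-month incidence table (raw, length-adjusted,
#' standardized) and its cosinor fit, optionally with a per-stratum
#' forest table: within each level of `by`, standardized monthly
#' incidence is refit separately and the zero-amplitude p-values are
#' Holm-adjusted across the levels of that stratification.
#'
#' @param cases Case data frame (ignored when `raw_counts` is given).
#' @param raw_counts Optional 12 monthly counts, January first.
#' @param by Optional name of a stratum column (e.g. `"sex"`,
#'   `"latitude_quartile"`; run [assign_strata()] first for derived
#'   strata).
#' @return A list of class `incidence_report`: `table` (the
#'   [monthly_incidence()] data frame), `fit` (the [cosinor()] fit),
#'   and, when `by` is given, `subgroups` — a data frame with one row
#'   per stratum: `stratum`, `n`, `amplitude`, `amplitude_lower`,
#'   `amplitude_upper`, `peak_month`, `p`, `p_holm`.
#' @export
incidence_report <- function(cases = NULL, raw_counts = NULL, by = NULL) {
  inc <- monthly_incidence(cases = cases, raw_counts = raw_counts)
  fit <- cosinor(inc$normalized_incidence)
  out <- list(table = inc, fit = fit)
  if (!is.null(by)) {
    if (is.null(cases)) stop("subgroup analysis needs case-level data")
    if (!by %in% names(cases)) stop("no such stratum column: ", by)
    levs <- sort(unique(cases[[by]][!is.na(cases[[by]])]))
    rows <- lapply(levs, function(lv) {
      sub <- cases[!is.na(cases[[by]]) & cases[[by]] == lv, , drop = FALSE]
      f <- cosinor(monthly_incidence(sub)$normalized_incidence)
      data.frame(stratum = lv, n = nrow(sub), amplitude = f$amplitude,
                 amplitude_lower = f$amplitude_ci[1],
                 amplitude_upper = f$amplitude_ci[2],
                 peak_month = f$peak_month, p = f$seasonality_p,
                 stringsAsFactors = FALSE)
    })
    sg <- do.call(rbind, rows)
    sg$p_holm <- holm_adjust(sg$p)
    out$subgroups <- sg
  }
  class(out) <- "incidence_report"
  out
}

#' @export
print.incidence_report <- function(x, digits = 3, ...) {
  print(x$table, digits = digits)
  cat("\n")
  print(x$fit)
  if (!is.null(x$subgroups)) {
    cat("\nSubgroup cosinor fits (Holm-adjusted p):\n")
    sg <- x$subgroups
    sg[c("amplitude", "amplitude_lower", "amplitude_upper")] <-
      lapply(sg[c("amplitude", "amplitude_lower", "amplitude_upper")],
             round, digits)
    sg$p <- signif(sg$p, digits); sg$p_holm <- signif(sg$p_holm, digits)
    print.data.frame(sg, row.names = FALSE)
  }
  invisible(x)
}

#' Seasonal mortality report
#'
#' Fits the winter-vs-summer mortality model for all cases and for the
#' northern and southern county halves, at each requested follow-up
#' horizon; the latitude-by-season interaction model; and (at the
#' first horizon, northern stratum) the peak-risk-month scan.
#'
#' @param cases Case data frame with survival fields.
#' @param scheme A [stratum_scheme()].
#' @param horizons Follow-up horizons in months; default `c(36, 60)`.
#' @param scan Run the sinusoid peak-month scan; default TRUE.
#' @param scan_stratum `"north"`, `"south"` or `"all"`; default
#'   `"north"`.
#' @param ... Passed to [fit_cox()] via the model constructors.
#' @return A list of class `survival_report`: `season_table` (one row
#'   per horizon and stratum with the winter-vs-summer HR, CI and p),
#'   `interaction` (list of `cox_fit`s by horizon), and `scan` (a
#'   [scan_peak_month()] result or NULL).
#' @export
survival_report <- function(cases, scheme = stratum_scheme(),
                            horizons = c(36, 60), scan = TRUE,
                            scan_stratum = "north", ...) {
  cases <- assign_strata(cases, scheme)
  strata <- list(`All cases` = rep(TRUE, nrow(cases)),
                 `North` = cases$north_south == "north",
                 `South` = cases$north_south == "south")
  rows <- list(); inter <- list()
  for (h in horizons) {
    for (snm in names(strata)) {
      f <- season_hr(cases[strata[[snm]], , drop = FALSE], h, scheme, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        horizon_months = h, stratum = snm,
        hr = f$hr[["winter"]],
        hr_lower = f$hr_ci["winter", "lower"],
        hr_upper = f$hr_ci["winter", "upper"],
        p = f$p[["winter"]], n = f$n, n_events = f$n_events,
        stringsAsFactors = FALSE)
    }
    inter[[as.character(h)]] <- latitude_interaction(cases, h, scheme = scheme, ...)
  }
  sc <- NULL
  if (isTRUE(scan)) {
    keep <- switch(scan_stratum, all = rep(TRUE, nrow(cases)),
                   north = cases$north_south == "north",
                   south = cases$north_south == "south",
                   stop("scan_stratum must be all/north/south"))
    sc <- scan_peak_month(cases[keep, , drop = FALSE], horizons[1], ...)
  }
  structure(list(season_table = do.call(rbind, rows), interaction = inter,
                 scan = sc),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, digits = 3, ...) {
  cat("Winter-vs-summer mortality hazard ratios:\n")
  st <- x$season_table
  st[c("hr", "hr_lower", "hr_upper")] <-
    lapply(st[c("hr", "hr_lower", "hr_upper")], round, digits)
  st$p <- signif(st$p, digits)
  print.data.frame(st, row.names = FALSE)
  for (h in names(x$interaction)) {
    f <- x$interaction[[h]]
    cat("\nSeason x latitude/10 interaction (", h, "-month horizon): HR ",
        round(f$hr[["season_x_lat10"]], digits), " [",
        round(f$hr_ci["season_x_lat10", "lower"], digits), ", ",
        round(f$hr_ci["season_x_lat10", "upper"], digits), "], p = ",
        signif(f$p[["season_x_lat10"]], digits), "\n", sep = "")
  }
  if (!is.null(x$scan)) { cat("\n"); print(x$scan, digits = digits) }
  invisible(x)
}

#' Write a cosinor fit as JSON
#'
#' @param fit A [cosinor()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cosinor_json <- function(fit, path) {
  jsonlite::write_json(list(
    mesor = fit$coefficients[[1]], amplitude = fit$amplitude,
    amplitude_ci = fit$amplitude_ci, acrophase = fit$acrophase,
    peak_month = fit$peak_month, trough_month = fit$trough_month,
    peak_trough_percent = as.numeric(peak_trough_percent(fit)),
    seasonality_p = fit$seasonality_p, n = fit$n, period = fit$period
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
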