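# Case-registry data model: CSV I/O, exclusion cascade, stratification.

#' Canonical case-listing columns
#'
#' Column names of the canonical case-listing schema used throughout
#' the package. `required = TRUE` columns must be present (possibly
#' via `column_map`) for [load_cases()] to succeed.
#'
#' @return A data frame with columns `column` and `required`.
#' @export
registry_schema <- function() {
  data.frame(
    column = c("case_id", "month_dx", "year_dx", "age_years", "sex",
               "histology", "stage", "county_id", "county_latitude",
               "survival_months", "event", "flags", "registry_id"),
    required = c(FALSE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, FALSE, TRUE,
                 TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

.sex_levels       <- c("male", "female")
.histology_levels <- c("lymphocyte-rich", "mixed-cellularity",
                       "lymphocyte-depleted", "nodular-sclerosis",
                       "NLPHL", "NOS")
.stage_levels     <- c("I", "II", "III", "IV")
.event_levels     <- c("death", "censored")
.flag_levels      <- c("death-certificate-only", "autopsy-only", "none")

.parse_level <- function(x, levels) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | x %in% c("NA", "na")] <- NA_character_
  bad <- !is.na(x) & !(x %in% levels)
  x[bad] <- NA_character_
  list(value = x, n_bad = sum(bad))
}

.parse_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  list(value = out, n_bad = sum(is.na(out) & !is.na(x) &
                                  nzchar(trimws(as.character(x))) &
                                  !trimws(as.character(x)) %in% c("NA", "na")))
}

#' Load a case-listing CSV
#'
#' Reads a registry case listing into the canonical schema. Columns
#' may be renamed through `column_map`, a named character vector of
#' the form `c(canonical = "name_in_file")`. Missing values are the
#' empty string or `"NA"`. Rows whose required fields do not parse
#' (e.g. a month outside 1--12, a negative survival time) are kept
#' with the offending field set to `NA` and tallied in the
#' `parse_report` attribute, never silently dropped; exclusion rules
#' decide their fate downstream.
#'
#' @param path Path to a UTF-8, comma-separated CSV with header row.
#' @param column_map Optional named character vector mapping canonical
#'   column names (see [registry_schema()]) to the names used in the
#'   file.
#' @return A data frame of cases in the canonical schema, with an
#'   attribute `parse_report` (data frame of per-column invalid-value
#'   counts, zero rows when everything parsed).
#' @export
load_cases <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty case listing: ", path)

  schema <- registry_schema()
  for (canon in names(column_map)) {
    if (!canon %in% schema$column)
      stop("unknown canonical column in column_map: ", canon)
    src <- column_map[[canon]]
    if (!src %in% names(raw))
      stop("column_map points to missing column: ", src)
    names(raw)[names(raw) == src] <- canon
  }
  missing_req <- setdiff(schema$column[schema$required], names(raw))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))

  n <- nrow(raw)
  get <- function(col, default) if (col %in% names(raw)) raw[[col]] else rep(default, n)

  month  <- .parse_num(raw$month_dx)
  badm   <- !is.na(month$value) & (month$value < 1 | month$value > 12 |
                                     month$value != round(month$value))
  month$value[badm] <- NA_real_
  month$n_bad <- month$n_bad + sum(badm)
  year   <- .parse_num(raw$year_dx)
  age    <- .parse_num(raw$age_years)
  bada   <- !is.na(age$value) & age$value < 0
  age$value[bada] <- NA_real_
  age$n_bad <- age$n_bad + sum(bada)
  surv   <- .parse_num(raw$survival_months)
  bads   <- !is.na(surv$value) & surv$value < 0
  surv$value[bads] <- NA_real_
  surv$n_bad <- surv$n_bad + sum(bads)
  lat    <- .parse_num(raw$county_latitude)
  badl   <- !is.na(lat$value) & (lat$value <= 0 | lat$value >= 90)
  lat$value[badl] <- NA_real_
  lat$n_bad <- lat$n_bad + sum(badl)
  sex    <- .parse_level(raw$sex, .sex_levels)
  hist   <- .parse_level(raw$histology, .histology_levels)
  stage  <- .parse_level(raw$stage, .stage_levels)
  event  <- .parse_level(raw$event, .event_levels)
  flags  <- .parse_level(get("flags", "none"), .flag_levels)
  flags$value[is.na(flags$value)] <- "none"

  cases <- data.frame(
    case_id         = as.character(get("case_id", NA)),
    month_dx        = as.integer(month$value),
    year_dx         = as.integer(year$value),
    age_years       = age$value,
    sex             = sex$value,
    histology       = hist$value,
    stage           = stage$value,
    county_id       = as.character(get("county_id", NA)),
    county_latitude = lat$value,
    survival_months = surv$value,
    event           = event$value,
    flags           = flags$value,
    registry_id     = as.character(get("registry_id", NA)),
    stringsAsFactors = FALSE
  )
  if (all(is.na(cases$case_id))) cases$case_id <- sprintf("case%06d", seq_len(n))

  rep_df <- data.frame(
    column = c("month_dx", "year_dx", "age_years", "survival_months",
               "county_latitude", "sex", "histology", "stage", "event"),
    n_invalid = c(month$n_bad, year$n_bad, age$n_bad, surv$n_bad,
                  lat$n_bad, sex$n_bad, hist$n_bad, stage$n_bad, event$n_bad),
    stringsAsFactors = FALSE
  )
  rep_df <- rep_df[rep_df$n_invalid > 0L, , drop = FALSE]
  if (nrow(rep_df))
    warning(sum(rep_df$n_invalid), " unparseable field value(s) set to NA; ",
            "see attr(, \"parse_report\")")
  attr(cases, "parse_report") <- rep_df
  cases
}

#' Write cases to a case-listing CSV
#'
#' Inverse of [load_cases()]: writes the canonical columns so a
#' write-then-load round trip preserves all fields. Output is
#' deterministic (no timestamps, fixed column order).
#'
#' @param cases Case data frame in the canonical schema.
#' @param path Output path.
#' @param manifest Optional list (e.g. a simulation config) written as
#'   JSON next to the CSV at `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(cases, path, manifest = NULL) {
  cols <- registry_schema()$column
  out <- cases[, intersect(cols, names(cases)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# ---- exclusion cascade -----------------------------------------------------

.known_rules <- c("dco-autopsy-only", "unknown-month", "excluded-registry",
                  "missing-age", "missing-stage")

.rule_drops <- function(cases, rule, ids = NULL) {
  switch(rule,
    "dco-autopsy-only"  = cases$flags %in% c("death-certificate-only", "autopsy-only"),
    "unknown-month"     = is.na(cases$month_dx),
    "excluded-registry" = {
      if (is.null(ids)) stop("excluded-registry rule needs registry ids")
      cases$registry_id %in% ids
    },
    "missing-age"       = is.na(cases$age_years),
    "missing-stage"     = is.na(cases$stage),
    stop("unknown exclusion rule: ", rule)
  )
}

#' Apply an ordered exclusion cascade
#'
#' Applies exclusion rules sequentially and records, for each rule in
#' order, how many cases it removed and how many remained. Rules are
#' given either as rule-name strings or as `list(rule = , ids = )` for
#' the registry rule. Known rules: `"dco-autopsy-only"` (cases known
#' only from a death certificate or autopsy), `"unknown-month"`,
#' `"excluded-registry"` (parameterized by registry ids, removed
#' together as one step), `"missing-age"`, `"missing-stage"`.
#'
#' @param cases Case data frame.
#' @param rules Ordered list of rules (see Details).
#' @return A list with `cohort` (the surviving cases) and `report`, an
#'   `exclusion_report` data frame with columns `rule`, `n_removed`,
#'   `n_remaining` whose accounting always satisfies
#'   `initial n = sum(n_removed) + final n_remaining`.
#' @export
apply_exclusions <- function(cases, rules = list()) {
  steps <- lapply(rules, function(r) {
    if (is.character(r)) r <- list(rule = r)
    if (is.null(r$rule) || !r$rule %in% .known_rules)
      stop("unknown exclusion rule: ", if (is.null(r$rule)) "<unnamed>" else r$rule)
    r
  })
  report <- data.frame(rule = character(0), n_removed = integer(0),
                       n_remaining = integer(0), stringsAsFactors = FALSE)
  initial_n <- nrow(cases)
  for (r in steps) {
    drop <- .rule_drops(cases, r$rule, r$ids)
    cases <- cases[!drop, , drop = FALSE]
    report <- rbind(report, data.frame(
      rule = r$rule, n_removed = sum(drop), n_remaining = nrow(cases),
      stringsAsFactors = FALSE))
  }
  attr(report, "initial_n") <- initial_n
  class(report) <- c("exclusion_report", "data.frame")
  list(cohort = cases, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade: ", attr(x, "initial_n"), " cases in, ",
      if (nrow(x)) x$n_remaining[nrow(x)] else attr(x, "initial_n"),
      " retained\n", sep = "")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write an exclusion report as JSON lines
#'
#' One JSON object per cascade step, with keys `rule`, `removed`,
#' `remaining`.
#'
#' @param report An `exclusion_report` from [apply_exclusions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  lines <- vapply(seq_len(nrow(report)), function(i) {
    jsonlite::toJSON(list(rule = report$rule[i],
                          removed = report$n_removed[i],
                          remaining = report$n_remaining[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- stratification --------------------------------------------------------

#' Latitude quartile cutpoints over distinct counties
#'
#' Sorts the distinct counties by latitude and splits them into four
#' groups of as-equal-as-possible size. The three cutpoints returned
#' are the latitudes of the first (southernmost) county of groups 2,
#' 3 and 4, so quartile intervals are half-open and lower-inclusive:
#' quartile 2 is `>= cut[1] & < cut[2]`, etc. Cases inherit the
#' quartile of their county. The study's own county set gives
#' cutpoints 34.19, 38.05, 41.68 degrees north; those are shipped as
#' the default in [stratum_scheme()] since the full county list is
#' not redistributable.
#'
#' @param counties Data frame with columns `county_id` and `latitude`
#'   (degrees north), or a numeric vector of latitudes.
#' @return Numeric vector of 3 increasing cutpoints.
#' @export
latitude_quartile_cutpoints <- function(counties) {
  lat <- if (is.data.frame(counties)) {
    counties <- counties[!duplicated(counties$county_id), , drop = FALSE]
    counties$latitude
  } else as.numeric(counties)
  lat <- sort(unique(lat))
  k <- length(lat)
  if (k < 4L) stop("need at least 4 distinct counties, got ", k)
  grp <- ceiling(4 * seq_len(k) / k)
  cut <- vapply(2:4, function(g) lat[match(g, grp)], numeric(1))
  if (any(diff(cut) <= 0)) stop("degenerate latitude distribution")
  cut
}

#' Stratification scheme
#'
#' Bundles the stratum definitions used throughout the analysis: age
#' group edges, latitude quartile cutpoints, the north/south split
#' (which reuses the middle quartile cutpoint, lower-inclusive for
#' north), the winter/summer half-year map (September--February is
#' winter, March--August summer, the meteorological convention), and
#' calendar-year bins.
#'
#' @param age_edges Increasing lower edges of the age groups; default
#'   `c(0, 20, 30, 40, 50, 60, 70)` giving 0--19, 20--29, ..., >=70.
#' @param latitude_cutpoints Three increasing quartile cutpoints in
#'   degrees north; default the study constants `c(34.19, 38.05, 41.68)`.
#' @param north_south_cutpoint Degrees north; `>=` is "north".
#'   Defaults to `latitude_cutpoints[2]`.
#' @param winter_months Integer months assigned to the winter
#'   half-year; default September--February.
#' @param year_edges Increasing lower edges of year-of-diagnosis bins
#'   (first bin open below); default `c(-Inf, 1990, 2000, 2010)`.
#' @return An object of class `stratum_scheme`.
#' @export
stratum_scheme <- function(age_edges = c(0, 20, 30, 40, 50, 60, 70),
                           latitude_cutpoints = c(34.19, 38.05, 41.68),
                           north_south_cutpoint = latitude_cutpoints[2],
                           winter_months = c(9:12, 1:2),
                           year_edges = c(-Inf, 1990, 2000, 2010)) {
  stopifnot(!is.unsorted(age_edges, strictly = TRUE),
            length(latitude_cutpoints) == 3L,
            !is.unsorted(latitude_cutpoints, strictly = TRUE),
            all(winter_months %in% 1:12),
            !is.unsorted(year_edges, strictly = TRUE))
  structure(list(age_edges = age_edges,
                 latitude_cutpoints = latitude_cutpoints,
                 north_south_cutpoint = north_south_cutpoint,
                 winter_months = as.integer(winter_months),
                 year_edges = year_edges),
            class = "stratum_scheme")
}

.edge_labels <- function(edges, last_open = TRUE, fmt = function(x) x) {
  k <- length(edges)
  labs <- character(k)
  for (i in seq_len(k - 1L))
    labs[i] <- paste0(fmt(edges[i]), "-", fmt(edges[i + 1L] - 1L))
  labs[k] <- paste0(">=", fmt(edges[k]))
  if (is.infinite(edges[1L])) labs[1L] <- paste0("<", fmt(edges[2L]))
  labs
}

#' Assign stratum labels to cases
#'
#' Adds `age_group`, `latitude_quartile` (`"Q1"`--`"Q4"`),
#' `north_south`, `season` (`"winter"`/`"summer"`) and `year_bin`
#' columns. Every case receives exactly one label per dimension;
#' latitudes below the first cutpoint fall in Q1 and at/above the
#' last in Q4 by the lower-inclusive boundary convention, never an
#' error.
#'
#' @param cases Case data frame.
#' @param scheme A [stratum_scheme()].
#' @return `cases` with the five stratum columns appended.
#' @export
assign_strata <- function(cases, scheme = stratum_scheme()) {
  stopifnot(inherits(scheme, "stratum_scheme"))
  age_lab <- .edge_labels(scheme$age_edges)
  cases$age_group <- age_lab[findInterval(cases$age_years, scheme$age_edges)]
  q <- findInterval(cases$county_latitude, scheme$latitude_cutpoints) + 1L
  cases$latitude_quartile <- ifelse(is.na(q), NA_character_, paste0("Q", q))
  cases$north_south <- ifelse(cases$county_latitude >= scheme$north_south_cutpoint,
                              "north", "south")
  cases$season <- ifelse(cases$month_dx %in% scheme$winter_months,
                         "winter", "summer")
  cases$season[is.na(cases$month_dx)] <- NA_character_
  year_lab <- .edge_labels(scheme$year_edges)
  cases$year_bin <- year_lab[findInterval(cases$year_dx, scheme$year_edges)]
  cases
}
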