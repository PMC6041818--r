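# Explore / Compare tabulations: the graph-ready data behind the
# disaggregated bar views, the trend-over-time view and the cross-setting
# benchmark view. Rendering itself is out of scope; these tables are what
# the plots would draw.

#' Detailed bar table for one stratum
#'
#' The disaggregated (detailed bar graph) view: one row per subgroup with
#' estimate and CI bounds, sortable by subgroup name or estimate in either
#' direction, optional median and/or setting-average reference lines, and
#' optional highlighted subgroups. Sorting is stable: equal estimates keep
#' name order. Values are never altered, only reordered.
#'
#' @param stratum An `ineq_stratum`.
#' @param sort_by `"subgroup"` (name) or `"estimate"`.
#' @param direction `"asc"` or `"desc"`.
#' @param reference_lines Character subset of
#'   `c("median", "setting_average")`. The median is the exact middle
#'   estimate (midpoint of the two middle values for even counts); the
#'   setting average comes from [setting_average()] and is `NA` when
#'   unavailable.
#' @param highlight Character vector of subgroup names to flag; an unknown
#'   name is an error listing the valid names.
#' @param axis_range Optional numeric `c(min, max)`.
#' @param title,axis_title Optional titles.
#' @return An `ineq_bar_table`: list with `rows` (tibble: `subgroup`,
#'   `estimate`, `ci_lb`, `ci_ub`, `highlighted`), `reference_lines`,
#'   `sort`, `axis_range`, `titles`.
#' @export
detailed_bar_table <- function(stratum,
                               sort_by = c("subgroup", "estimate"),
                               direction = c("asc", "desc"),
                               reference_lines = character(),
                               highlight = character(),
                               axis_range = NULL,
                               title = NULL,
                               axis_title = NULL) {
  stopifnot(inherits(stratum, "ineq_stratum"))
  sort_by <- match.arg(sort_by)
  direction <- match.arg(direction)
  bad_ref <- setdiff(reference_lines, c("median", "setting_average"))
  if (length(bad_ref) > 0) {
    stop("unknown reference line(s): ", paste(bad_ref, collapse = ", "),
         "; valid: median, setting_average", call. = FALSE)
  }
  s <- stratum$subgroups
  unknown <- setdiff(highlight, s$subgroup)
  if (length(unknown) > 0) {
    stop("unknown subgroup(s) in highlight: ",
         paste(unknown, collapse = ", "), "; valid subgroups: ",
         paste(s$subgroup, collapse = ", "), call. = FALSE)
  }

  o <- if (sort_by == "subgroup") {
    order(s$subgroup, decreasing = (direction == "desc"))
  } else if (direction == "asc") {
    order(s$estimate, s$subgroup)
  } else {
    order(-s$estimate, s$subgroup)
  }
  rows <- tibble::tibble(
    subgroup = s$subgroup[o],
    estimate = s$estimate[o],
    ci_lb = s$ci_lb[o],
    ci_ub = s$ci_ub[o],
    highlighted = s$subgroup[o] %in% highlight
  )
  refs <- list()
  if ("median" %in% reference_lines) refs$median <- median(s$estimate)
  if ("setting_average" %in% reference_lines) {
    refs$setting_average <- setting_average(stratum)
  }
  structure(
    list(rows = rows,
         reference_lines = refs,
         sort = list(key = sort_by, direction = direction),
         axis_range = axis_range,
         titles = list(main = title, axis = axis_title),
         stratum_key = list(setting = stratum$setting, year = stratum$year,
                            source = stratum$source,
                            indicator_abbr = stratum$indicator_abbr,
                            dimension = stratum$dimension)),
    class = "ineq_bar_table")
}

#' @export
print.ineq_bar_table <- function(x, ...) {
  k <- x$stratum_key
  cat("<ineq_bar_table> ", k$setting, " ", k$year, " | ", k$indicator_abbr,
      " | ", k$dimension, " (sorted by ", x$sort$key, " ",
      x$sort$direction, ")\n", sep = "")
  print(x$rows, ...)
  for (nm in names(x$reference_lines)) {
    cat("  ", nm, " line: ", format(x$reference_lines[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

#' Per-year bar tables for a trend view
#'
#' One [detailed_bar_table()] per available year for a setting x indicator
#' x dimension selection, in ascending year order. Years with no stratum
#' are absent, never interpolated. When the same year is covered by
#' several sources the alphabetically first source is used.
#'
#' @param dataset An [ineq_data] object.
#' @param setting,indicator_abbr,dimension Selection.
#' @param ... Passed to [detailed_bar_table()].
#' @return Named list of `ineq_bar_table` (names are years). An empty
#'   selection returns an empty list with a `"diagnostic"` attribute.
#' @export
trend_table <- function(dataset, setting, indicator_abbr, dimension, ...) {
  strata <- stratify(dataset)
  keep <- Filter(function(st)
    st$setting == setting && st$indicator_abbr == indicator_abbr &&
      st$dimension == dimension, strata)
  if (length(keep) == 0) {
    out <- list()
    attr(out, "diagnostic") <- paste0(
      "no strata match setting '", setting, "', indicator '",
      indicator_abbr, "', dimension '", dimension, "'")
    return(out)
  }
  years <- vapply(keep, function(st) st$year, numeric(1))
  sources <- vapply(keep, function(st) st$source, character(1))
  out <- list()
  for (y in sort(unique(years))) {
    cand <- which(years == y)
    st <- keep[[cand[order(sources[cand])][1]]]
    out[[as.character(y)]] <- detailed_bar_table(st, ...)
  }
  out
}

#' Cross-setting benchmark table
#'
#' The benchmark view: one row per setting pairing the setting average
#' with one summary-measure value, the data behind a "national average vs
#' inequality" scatter. For each setting the latest year with a stratum
#' for the chosen indicator x dimension is used (alphabetically first
#' source on ties). Settings can be filtered by tags (e.g. region, income
#' group) supplied in a side table, since such metadata is not part of the
#' template. Settings for which the measure is not applicable or skipped
#' are omitted, with the reason recorded in the `"notes"` attribute.
#'
#' @param dataset An [ineq_data] object.
#' @param measure A single measure identifier from [measure_info()].
#' @param indicator_abbr,dimension Selection.
#' @param settings_info Optional tibble keyed by `setting` carrying tag
#'   columns (see [setting_info()]).
#' @param filter Optional named list of tag values; a setting is kept when
#'   every named column matches one of the given values.
#' @return An `ineq_compare_table`: tibble with columns `setting`, `iso3`,
#'   `year`, `setting_average`, `measure`, `value`; omitted settings in
#'   attribute `"notes"`, the filter description in attribute
#'   `"benchmark_filter"`.
#' @export
compare_table <- function(dataset, measure, indicator_abbr, dimension,
                          settings_info = NULL, filter = NULL) {
  stopifnot(length(measure) == 1)
  if (!measure %in% MEASURE_IDS) {
    stop("unknown measure '", measure, "'; valid measures: ",
         paste(MEASURE_IDS, collapse = ", "), call. = FALSE)
  }
  strata <- stratify(dataset)
  keep <- Filter(function(st)
    st$indicator_abbr == indicator_abbr && st$dimension == dimension,
    strata)
  settings <- sort(unique(vapply(keep, function(st) st$setting,
                                 character(1))))
  notes <- character()

  if (!is.null(filter)) {
    if (is.null(settings_info)) {
      stop("a filter requires settings_info", call. = FALSE)
    }
    info <- tibble::as_tibble(settings_info)
    ok <- settings %in% info$setting
    notes <- c(notes, if (any(!ok))
      paste0("setting '", settings[!ok], "' absent from settings_info"))
    settings <- settings[ok]
    for (col in names(filter)) {
      vals <- info[[col]][match(settings, info$setting)]
      settings <- settings[vals %in% filter[[col]]]
    }
  }

  rows <- list()
  for (s in settings) {
    cand <- Filter(function(st) st$setting == s, keep)
    years <- vapply(cand, function(st) st$year, numeric(1))
    latest <- cand[years == max(years)]
    srcs <- vapply(latest, function(st) st$source, character(1))
    st <- latest[[order(srcs)[1]]]
    res <- compute_stratum(st, measures = measure)
    if (nrow(res) == 0) {
      reason <- skipped_measures(res)
      notes <- c(notes, paste0(
        "setting '", s, "' omitted: ", measure, " ",
        if (nrow(reason) > 0) reason$reason[1] else "unavailable"))
      next
    }
    iso <- dataset$iso3[dataset$setting == s & !is.na(dataset$iso3)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      setting = s,
      iso3 = if (length(iso)) iso[1] else NA_character_,
      year = st$year,
      setting_average = setting_average(st),
      measure = measure,
      value = res$value[1])
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(setting = character(), iso3 = character(),
                   year = numeric(), setting_average = numeric(),
                   measure = character(), value = numeric())
  if (nrow(out) == 0) notes <- c(notes, "no settings matched")
  structure(out,
            class = c("ineq_compare_table", class(tibble::tibble())),
            notes = notes,
            benchmark_filter = if (is.null(filter)) "all settings" else
              paste(names(filter),
                    vapply(filter, function(v)
                      paste(v, collapse = "|"), character(1)),
                    sep = " = ", collapse = "; "))
}

#' Write an explore table as CSV or TSV
#'
#' Writes the rows of a bar table, a named list of bar tables (trend view;
#' a `year` column is added), or a compare table.
#'
#' @param x An `ineq_bar_table`, a list of them, or an
#'   `ineq_compare_table`.
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- if (inherits(x, "ineq_bar_table")) {
    x$rows
  } else if (inherits(x, "ineq_compare_table")) {
    tibble::as_tibble(x)
  } else if (is.list(x)) {
    dplyr::bind_rows(lapply(names(x), function(y)
      dplyr::bind_cols(tibble::tibble(year = as.numeric(y)), x[[y]]$rows)))
  } else {
    tibble::as_tibble(x)
  }
  if (format == "csv") {
    readr::write_csv(df, path, na = "", progress = FALSE)
  } else {
    readr::write_tsv(df, path, na = "", progress = FALSE)
  }
  invisible(path)
}
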