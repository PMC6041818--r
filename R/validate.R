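# Template contract validation.
#
# Errors block acceptance; missing recommended/optional variables only warn.
# Row-level checks run first (mandatory cells present and parseable, flag
# domains, CI ordering); stratum-level checks then run on the rows that
# parsed (constant indicator metadata, subgroup_order sequencing, reference
# subgroup uniqueness, >= 2 subgroups).

#' Validate raw template rows
#'
#' Checks raw rows (from [read_indicator_table()] or [generate_dataset()])
#' against the template contract and returns a validation report. The
#' report carries the accepted dataset when, and only when, no errors were
#' found; data problems never throw.
#'
#' Row-level rules: the 13 mandatory variables must be present and
#' parseable for every observation; `favourable_indicator`,
#' `ordered_dimension` and `reference_subgroup` must be 0 or 1;
#' `indicator_scale` must be positive; an ordered row needs
#' `subgroup_order >= 1` and `reference_subgroup = 0`, a non-ordered row
#' needs `subgroup_order = 0`; CI bounds, when both present, must bracket
#' the estimate. Stratum-level rules (a stratum is one setting x year x
#' source x indicator x dimension): indicator metadata constant across the
#' stratum; at least two subgroups; no duplicated subgroup; for ordered
#' strata the `subgroup_order` values must be distinct positive integers
#' starting at 1 (gaps allowed, with a warning) and a dimension with
#' exactly two subgroups must not be flagged ordered; at most one
#' reference subgroup. Missing `se`, `population` or `setting_average`
#' values produce warnings only — without population the dataset degrades
#' to unweighted summary measures downstream.
#'
#' @param raw A tibble of character columns as returned by
#'   [read_indicator_table()], or an already-typed template tibble.
#' @param name Name under which the dataset is stored.
#' @return An object of class `ineq_validation`: a list with `errors`
#'   (tibble: `row`, `column`, `code`, `message`), `warnings` (tibble:
#'   `scope`, `code`, `message`), `accepted` (logical) and `dataset` (an
#'   [ineq_data] when accepted, otherwise `NULL`).
#' @export
#' @examples
#' raw <- generate_dataset(scenario_spec(n_settings = 1))
#' rep <- validate_indicator_data(raw, name = "demo")
#' rep$accepted
validate_indicator_data <- function(raw, name = "dataset") {
  raw <- tibble::as_tibble(raw)
  errors <- list()
  warnings <- list()
  err <- function(row, column, code, message) {
    errors[[length(errors) + 1L]] <<- tibble::tibble(
      row = as.integer(row), column = column, code = code, message = message)
  }
  warn <- function(scope, code, message) {
    warnings[[length(warnings) + 1L]] <<- tibble::tibble(
      scope = scope, code = code, message = message)
  }

  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  for (col in missing_cols) {
    err(NA, col, "missing_mandatory_column",
        paste0("mandatory column '", col, "' is absent"))
  }
  for (col in setdiff(RECOMMENDED_COLUMNS, names(raw))) {
    warn("dataset", paste0("no_", col),
         paste0("recommended column '", col, "' is absent"))
  }
  for (col in setdiff(TEMPLATE_COLUMNS, names(raw))) {
    raw[[col]] <- NA_character_
  }
  if (nrow(raw) == 0) {
    err(NA, NA_character_, "empty_dataset", "no data rows")
  }

  rows <- parse_template_types(raw)

  if (length(missing_cols) == 0 && nrow(rows) > 0) {
    check_row_level(rows, err)
    check_stratum_level(rows, err, warn)
    check_availability(rows, warn)
  }

  errors <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(row = integer(), column = character(),
                   code = character(), message = character())
  warnings <- if (length(warnings)) dplyr::bind_rows(warnings) else
    tibble::tibble(scope = character(), code = character(),
                   message = character())
  accepted <- nrow(errors) == 0

  structure(
    list(
      name = name,
      errors = errors,
      warnings = warnings,
      accepted = accepted,
      dataset = if (accepted) new_ineq_data(rows, name) else NULL
    ),
    class = "ineq_validation"
  )
}

# type the raw character cells; unparseable numeric cells become NA here and
# are reported by check_row_level (which re-inspects the raw text)
parse_template_types <- function(raw) {
  rows <- raw[, TEMPLATE_COLUMNS]
  for (col in NUMERIC_COLUMNS) {
    if (is.character(rows[[col]])) {
      rows[[col]] <- suppressWarnings(as.numeric(rows[[col]]))
    } else {
      rows[[col]] <- as.numeric(rows[[col]])
    }
  }
  for (col in setdiff(TEMPLATE_COLUMNS, NUMERIC_COLUMNS)) {
    rows[[col]] <- as.character(rows[[col]])
  }
  attr(rows, "raw_text") <- raw
  rows
}

check_row_level <- function(rows, err) {
  raw <- attr(rows, "raw_text")
  n <- nrow(rows)
  for (col in MANDATORY_COLUMNS) {
    raw_col <- as.character(raw[[col]])
    missing <- is.na(raw_col)
    for (i in which(missing)) {
      err(i, col, "missing_mandatory",
          paste0("mandatory value '", col, "' missing in row ", i))
    }
    if (col %in% NUMERIC_COLUMNS) {
      bad <- !missing & is.na(rows[[col]])
      for (i in which(bad)) {
        err(i, col, "unparseable_number",
            paste0("'", raw_col[i], "' in column '", col,
                   "' is not a number (row ", i, ")"))
      }
    }
  }
  # recommended/optional numeric cells that are present but not numbers
  for (col in intersect(NUMERIC_COLUMNS, c(RECOMMENDED_COLUMNS, "ci_lb", "ci_ub"))) {
    raw_col <- as.character(raw[[col]])
    bad <- !is.na(raw_col) & is.na(rows[[col]]) & col != "iso3"
    for (i in which(bad)) {
      err(i, col, "unparseable_number",
          paste0("'", raw_col[i], "' in column '", col,
                 "' is not a number (row ", i, ")"))
    }
  }

  flag01 <- function(col, code) {
    v <- rows[[col]]
    bad <- !is.na(v) & !v %in% c(0, 1)
    for (i in which(bad)) {
      err(i, col, code,
          paste0(col, " must be 0 or 1, found ", v[i], " (row ", i, ")"))
    }
  }
  flag01("favourable_indicator", "bad_favourable_flag")
  flag01("ordered_dimension", "bad_ordered_flag")
  flag01("reference_subgroup", "bad_reference_flag")

  bad_scale <- !is.na(rows$indicator_scale) & rows$indicator_scale <= 0
  for (i in which(bad_scale)) {
    err(i, "indicator_scale", "bad_indicator_scale",
        paste0("indicator_scale must be positive, found ",
               rows$indicator_scale[i], " (row ", i, ")"))
  }

  so <- rows$subgroup_order
  bad_int <- !is.na(so) & (so < 0 | so != round(so))
  for (i in which(bad_int)) {
    err(i, "subgroup_order", "bad_subgroup_order",
        paste0("subgroup_order must be a non-negative integer, found ",
               so[i], " (row ", i, ")"))
  }
  ord <- rows$ordered_dimension
  bad_ord_so <- !is.na(ord) & !is.na(so) & ord == 1 & so < 1
  for (i in which(bad_ord_so)) {
    err(i, "subgroup_order", "bad_subgroup_order",
        paste0("ordered dimensions need subgroup_order >= 1 (row ", i, ")"))
  }
  bad_non_so <- !is.na(ord) & !is.na(so) & ord == 0 & so != 0
  for (i in which(bad_non_so)) {
    err(i, "subgroup_order", "bad_subgroup_order",
        paste0("subgroup_order must be 0 for non-ordered and binary ",
               "dimensions (row ", i, ")"))
  }
  ref <- rows$reference_subgroup
  bad_ord_ref <- !is.na(ord) & !is.na(ref) & ord == 1 & ref != 0
  for (i in which(bad_ord_ref)) {
    err(i, "reference_subgroup", "bad_reference_flag",
        paste0("reference_subgroup must be 0 for ordered dimensions (row ",
               i, ")"))
  }

  bad_se <- !is.na(rows$se) & rows$se < 0
  for (i in which(bad_se)) {
    err(i, "se", "negative_se",
        paste0("se must be >= 0, found ", rows$se[i], " (row ", i, ")"))
  }
  bad_pop <- !is.na(rows$population) & rows$population <= 0
  for (i in which(bad_pop)) {
    err(i, "population", "nonpositive_population",
        paste0("population must be > 0, found ", rows$population[i],
               " (row ", i, ")"))
  }
  bad_ci <- !is.na(rows$ci_lb) & !is.na(rows$ci_ub) & !is.na(rows$estimate) &
    !(rows$ci_lb <= rows$estimate & rows$estimate <= rows$ci_ub)
  for (i in which(bad_ci)) {
    err(i, "ci_lb", "bad_ci_order",
        paste0("95% CI must bracket the estimate (row ", i, ")"))
  }
}

check_stratum_level <- function(rows, err, warn) {
  idx <- seq_len(nrow(rows))
  key <- stratum_label(rows)
  for (k in unique(key)) {
    in_k <- idx[key == k]
    g <- rows[in_k, ]

    dup <- duplicated(g$subgroup)
    for (i in in_k[dup]) {
      err(i, "subgroup", "duplicate_subgroup",
          paste0("duplicated subgroup '", rows$subgroup[i], "' in stratum ",
                 k))
    }
    if (nrow(g) < 2) {
      err(in_k[1], "subgroup", "single_subgroup",
          paste0("stratum ", k, " has fewer than 2 subgroups"))
    }
    for (col in c("favourable_indicator", "indicator_scale",
                  "ordered_dimension", "indicator_name")) {
      if (dplyr::n_distinct(g[[col]], na.rm = TRUE) > 1) {
        err(in_k[1], col, "inconsistent_stratum",
            paste0(col, " is not constant within stratum ", k))
      }
    }
    avg <- unique(g$setting_average[!is.na(g$setting_average)])
    if (length(avg) > 1) {
      warn(k, "inconsistent_setting_average",
           paste0("setting_average varies within stratum ", k,
                  "; the first value is used"))
    }

    ordered <- isTRUE(g$ordered_dimension[1] == 1)
    if (ordered) {
      if (nrow(g) == 2) {
        err(in_k[1], "ordered_dimension", "ordered_binary",
            paste0("stratum ", k, " has two subgroups; ordered_dimension ",
                   "must be 0 for binary dimensions"))
      }
      so <- sort(g$subgroup_order[!is.na(g$subgroup_order)])
      if (length(so) == nrow(g) && all(so >= 1)) {
        if (anyDuplicated(so) || so[1] != 1) {
          err(in_k[1], "subgroup_order", "bad_subgroup_order",
              paste0("subgroup_order in stratum ", k, " must be an ",
                     "increasing sequence of integers starting at 1"))
        } else if (length(so) > 1 && any(diff(so) > 1)) {
          warn(k, "subgroup_order_gaps",
               paste0("subgroup_order in stratum ", k,
                      " has gaps; ranks follow the sort order"))
        }
      }
    } else {
      n_ref <- sum(g$reference_subgroup == 1, na.rm = TRUE)
      if (n_ref > 1) {
        err(in_k[1], "reference_subgroup", "multiple_reference_subgroups",
            paste0("stratum ", k, " designates ", n_ref,
                   " reference subgroups; at most one is allowed"))
      }
    }
  }
}

check_availability <- function(rows, warn) {
  for (col in c("se", "population", "setting_average")) {
    n_missing <- sum(is.na(rows[[col]]))
    if (n_missing == nrow(rows)) {
      warn("dataset", paste0("no_", col),
           paste0("'", col, "' is missing for all observations"))
    } else if (n_missing > 0) {
      warn("dataset", paste0("partial_", col),
           paste0("'", col, "' is missing for ", n_missing, " of ",
                  nrow(rows), " observations"))
    }
  }
}

stratum_label <- function(rows) {
  paste(rows$setting, rows$year, rows$source, rows$indicator_abbr,
        rows$dimension, sep = " | ")
}

#' @export
print.ineq_validation <- function(x, ...) {
  status <- if (x$accepted) "accepted" else "rejected"
  cat("<ineq_validation> dataset '", x$name, "': ", status, "\n", sep = "")
  cat("  errors:   ", nrow(x$errors), "\n", sep = "")
  cat("  warnings: ", nrow(x$warnings), "\n", sep = "")
  if (nrow(x$errors) > 0) {
    print(head(x$errors, 10))
  }
  invisible(x)
}

#' Write a validation report to disk
#'
#' Writes the report both as JSON lines (one record per error/warning, for
#' machines) and as human-readable text.
#'
#' @param report An `ineq_validation` object.
#' @param json_path Path for the JSON-lines report, or `NULL` to skip.
#' @param text_path Path for the text report, or `NULL` to skip.
#' @return The report, invisibly.
#' @export
write_validation_report <- function(report, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(report, "ineq_validation"))
  if (!is.null(json_path)) {
    recs <- c(
      list(list(type = "summary", dataset = report$name,
                accepted = report$accepted,
                n_errors = nrow(report$errors),
                n_warnings = nrow(report$warnings))),
      lapply(seq_len(nrow(report$errors)), function(i) {
        r <- report$errors[i, ]
        list(type = "error", row = r$row, column = r$column,
             code = r$code, message = r$message)
      }),
      lapply(seq_len(nrow(report$warnings)), function(i) {
        r <- report$warnings[i, ]
        list(type = "warning", scope = r$scope, code = r$code,
             message = r$message)
      })
    )
    lines <- vapply(recs, function(r)
      jsonlite::toJSON(r, auto_unbox = TRUE, na = "null"), character(1))
    writeLines(lines, json_path)
  }
  if (!is.null(text_path)) {
    lines <- c(
      paste0("dataset '", report$name, "': ",
             if (report$accepted) "accepted" else "rejected"),
      paste0(nrow(report$errors), " error(s), ",
             nrow(report$warnings), " warning(s)"),
      if (nrow(report$errors) > 0)
        paste0("ERROR [", report$errors$code, "] ", report$errors$message),
      if (nrow(report$warnings) > 0)
        paste0("WARNING [", report$warnings$code, "] ",
               report$warnings$message)
    )
    writeLines(lines, text_path)
  }
  invisible(report)
}
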