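#' Read an upload-template file
#'
#' Reads a disaggregated-data file in the upload template from CSV or Excel
#' (`.xls`/`.xlsx`). All cells are returned as text; typing and the template
#' contract are enforced later by [validate_indicator_data()]. Header
#' matching is case-insensitive and whitespace-trimmed, and the confidence
#' bound columns are accepted both as `95ci_lb`/`95ci_ub` (the template
#' spelling) and `ci_lb`/`ci_ub`. Unrecognised columns are preserved but
#' ignored downstream.
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (use the file extension), `"csv"`, `"xls"`
#'   or `"xlsx"`.
#' @return A tibble of character columns, one row per data line, with
#'   recognised columns renamed to their canonical names and an attribute
#'   `"unknown_columns"` listing any unrecognised headers.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_indicator_data(generate_dataset(scenario_spec(n_settings = 1)), path)
#' raw <- read_indicator_table(path)
#' nrow(raw)
read_indicator_table <- function(path, format = c("auto", "csv", "xls", "xlsx")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("csv", "xls", "xlsx")) {
      stop("unsupported format '.", ext,
           "': expected .csv, .xls or .xlsx", call. = FALSE)
    }
    format <- ext
  }

  raw <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, name_repair = "minimal",
                    na = character())
  } else {
    readxl::read_excel(path, col_types = "text", .name_repair = "minimal")
  }
  raw <- tibble::as_tibble(raw, .name_repair = "minimal")
  if (ncol(raw) == 0) {
    stop("missing header row: no columns found in ", path, call. = FALSE)
  }

  header <- trimws(tolower(names(raw)))
  canonical <- ifelse(header %in% names(COLUMN_ALIASES),
                      COLUMN_ALIASES[header], header)
  dup <- canonical[duplicated(canonical) & canonical %in% TEMPLATE_COLUMNS]
  if (length(dup) > 0) {
    stop("duplicated header names: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  names(raw) <- canonical

  # normalise cells: trim; "", "NA" and empty cells are missing, nothing else
  raw[] <- lapply(raw, function(x) {
    x <- trimws(as.character(x))
    x[x %in% c("", "NA")] <- NA_character_
    x
  })

  unknown <- setdiff(canonical, TEMPLATE_COLUMNS)
  attr(raw, "unknown_columns") <- unknown
  attr(raw, "source_path") <- path
  raw
}

#' Write a validated dataset as a canonical template CSV
#'
#' Persists a dataset (or the raw tibble returned by [generate_dataset()])
#' as CSV in the canonical 20-column template order, with the on-disk
#' headers (`95ci_lb`/`95ci_ub`) and numbers rendered at full precision so
#' that a write/read round trip reproduces every value bit-identically.
#'
#' @param data An `ineq_data` object or a raw template tibble.
#' @param path Output file path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_indicator_data <- function(data, path) {
  rows <- if (inherits(data, "ineq_data")) dataset_rows(data) else data
  out <- tibble::as_tibble(rows)[, TEMPLATE_COLUMNS]
  names(out) <- TEMPLATE_HEADERS
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
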