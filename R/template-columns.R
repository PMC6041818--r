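# Template column contract.
#
# Internal canonical names for the 20 template columns; on disk the CI bound
# columns are headed "95ci_lb"/"95ci_ub" (leading digits are hostile to many
# tools, so internally they are ci_lb/ci_ub and both spellings are accepted
# on input).

TEMPLATE_COLUMNS <- c(
  "setting", "year", "source", "indicator_abbr", "indicator_name",
  "dimension", "subgroup", "estimate", "se", "population",
  "setting_average", "iso3", "ci_lb", "ci_ub", "flag",
  "favourable_indicator", "indicator_scale", "ordered_dimension",
  "subgroup_order", "reference_subgroup"
)

MANDATORY_COLUMNS <- c(
  "setting", "year", "source", "indicator_abbr", "indicator_name",
  "dimension", "subgroup", "estimate", "favourable_indicator",
  "indicator_scale", "ordered_dimension", "subgroup_order",
  "reference_subgroup"
)

RECOMMENDED_COLUMNS <- c("se", "population", "setting_average", "iso3")

# header spellings accepted on input (after lower-casing and trimming),
# mapped to canonical names
COLUMN_ALIASES <- c(
  "95ci_lb" = "ci_lb", "95ci_ub" = "ci_ub",
  "ci_lb" = "ci_lb", "ci_ub" = "ci_ub"
)

# header used when writing the canonical template CSV/XLSX
TEMPLATE_HEADERS <- ifelse(
  TEMPLATE_COLUMNS %in% c("ci_lb", "ci_ub"),
  paste0("95", TEMPLATE_COLUMNS),
  TEMPLATE_COLUMNS
)

# columns parsed as numbers during validation
NUMERIC_COLUMNS <- c(
  "year", "estimate", "se", "population", "setting_average", "ci_lb",
  "ci_ub", "favourable_indicator", "indicator_scale", "ordered_dimension",
  "subgroup_order", "reference_subgroup"
)

STRATUM_KEY <- c("setting", "year", "source", "indicator_abbr", "dimension")

#' Canonical template columns
#'
#' Returns the 20 columns of the upload template in canonical order, with
#' their role (mandatory, recommended, optional) and the header spelling
#' used on disk.
#'
#' @return A tibble with columns `column`, `header` and `role`.
#' @export
#' @examples
#' template_columns()
template_columns <- function() {
  tibble::tibble(
    column = TEMPLATE_COLUMNS,
    header = TEMPLATE_HEADERS,
    role = dplyr::case_when(
      TEMPLATE_COLUMNS %in% MANDATORY_COLUMNS ~ "mandatory",
      TEMPLATE_COLUMNS %in% RECOMMENDED_COLUMNS ~ "recommended",
      TRUE ~ "optional"
    )
  )
}
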