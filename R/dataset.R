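# Validated dataset and stratum containers.

new_ineq_data <- function(rows, name) {
  # drop incidental attributes (source path, generator ground truth, ...)
  rows <- tibble::as_tibble(rows)[, TEMPLATE_COLUMNS]
  for (a in setdiff(names(attributes(rows)),
                    c("names", "row.names", "class"))) {
    attr(rows, a) <- NULL
  }
  structure(rows,
            class = c("ineq_data", class(tibble::tibble())),
            dataset_name = name)
}

#' Dataset accessors
#'
#' An `ineq_data` is a validated dataset: a tibble of template rows (one
#' subgroup estimate per row) that passed [validate_indicator_data()],
#' stored under a user-supplied name.
#'
#' @param x An `ineq_data` object.
#' @return `dataset_name()` returns the stored name; `dataset_rows()` the
#'   underlying tibble without the class decoration.
#' @name ineq_data
NULL

#' @rdname ineq_data
#' @export
dataset_name <- function(x) attr(x, "dataset_name")

#' @rdname ineq_data
#' @export
dataset_rows <- function(x) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "dataset_name") <- NULL
  out
}

#' @export
print.ineq_data <- function(x, ...) {
  cat("<ineq_data> '", dataset_name(x), "': ", nrow(x), " observations, ",
      length(stratify(x)), " strata\n", sep = "")
  print(dataset_rows(x), ...)
  invisible(x)
}

#' Partition a validated dataset into strata
#'
#' A stratum is the unit on which summary measures are computed: all
#' subgroups for one setting x year x source x indicator x dimension. The
#' dimension type is derived per stratum: `binary` for exactly two
#' subgroups, `ordered` when `ordered_dimension = 1`, otherwise
#' `nonordered`. Subgroups in an ordered stratum are sorted by ascending
#' `subgroup_order` (most disadvantaged first); other strata are sorted by
#' subgroup name, so row order in the input file never matters.
#'
#' @param dataset An [ineq_data] object.
#' @return A list of `ineq_stratum` objects, ordered by stratum key.
#' @export
#' @examples
#' d <- validate_indicator_data(generate_dataset(scenario_spec()))$dataset
#' length(stratify(d))
stratify <- function(dataset) {
  stopifnot(inherits(dataset, "ineq_data"))
  rows <- dataset_rows(dataset)
  key <- stratum_label(rows)
  lapply(sort(unique(key)), function(k) {
    new_stratum(rows[key == k, ])
  })
}

new_stratum <- function(g) {
  ordered <- g$ordered_dimension[1] == 1
  type <- if (nrow(g) == 2) "binary" else if (ordered) "ordered" else "nonordered"
  ord <- if (ordered) order(g$subgroup_order) else order(g$subgroup)
  g <- g[ord, ]
  avg <- g$setting_average[!is.na(g$setting_average)]
  structure(
    list(
      setting = g$setting[1],
      year = g$year[1],
      source = g$source[1],
      indicator_abbr = g$indicator_abbr[1],
      indicator_name = g$indicator_name[1],
      dimension = g$dimension[1],
      dimension_type = type,
      favourable = g$favourable_indicator[1] == 1,
      scale = g$indicator_scale[1],
      setting_average_provided = if (length(avg)) avg[1] else NA_real_,
      subgroups = tibble::tibble(
        subgroup = g$subgroup,
        estimate = g$estimate,
        se = g$se,
        population = g$population,
        order = g$subgroup_order,
        reference = !is.na(g$reference_subgroup) & g$reference_subgroup == 1,
        ci_lb = g$ci_lb,
        ci_ub = g$ci_ub
      )
    ),
    class = "ineq_stratum"
  )
}

#' @export
print.ineq_stratum <- function(x, ...) {
  cat("<ineq_stratum> ", x$setting, " ", x$year, " | ", x$source, " | ",
      x$indicator_abbr, " | ", x$dimension, " (", x$dimension_type,
      if (x$favourable) ", favourable" else ", adverse", ")\n", sep = "")
  print(x$subgroups, ...)
  invisible(x)
}

# availability flags used by the applicability matrix
stratum_has_population <- function(stratum) {
  all(!is.na(stratum$subgroups$population))
}
stratum_has_se <- function(stratum) {
  all(!is.na(stratum$subgroups$se))
}
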