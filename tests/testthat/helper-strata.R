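# Build strata directly (bypassing the validator) so measure formulas can
# be exercised on hand-picked configurations, plus a randomized stratum
# generator for the property suite.

make_stratum <- function(y, pop = NULL, se = NULL, type = NULL,
                         favourable = TRUE, order = NULL, reference = NULL,
                         avg = NA_real_, scale = 100, names = NULL) {
  j <- length(y)
  if (is.null(type)) {
    type <- if (!is.null(order)) "ordered"
    else if (j == 2) "binary" else "nonordered"
  }
  if (type == "ordered" && is.null(order)) order <- seq_len(j)
  if (is.null(names)) names <- sprintf("G%02d", seq_len(j))
  ref <- rep(FALSE, j)
  if (!is.null(reference)) {
    ref[if (is.character(reference)) match(reference, names) else reference] <- TRUE
  }
  structure(
    list(
      setting = "Testland", year = 2015, source = "TEST",
      indicator_abbr = "ind", indicator_name = "Test indicator",
      dimension = "dim", dimension_type = type, favourable = favourable,
      scale = scale, setting_average_provided = avg,
      subgroups = tibble::tibble(
        subgroup = names, estimate = as.numeric(y),
        se = if (is.null(se)) NA_real_ else as.numeric(se),
        population = if (is.null(pop)) NA_real_ else as.numeric(pop),
        order = if (is.null(order)) 0 else as.numeric(order),
        reference = ref, ci_lb = NA_real_, ci_ub = NA_real_)
    ),
    class = "ineq_stratum")
}

random_stratum <- function(type = NULL, with_pop = TRUE, with_se = TRUE,
                           constant = FALSE, max_pop = 5000) {
  if (is.null(type)) type <- sample(c("binary", "ordered", "nonordered"), 1)
  j <- switch(type, binary = 2L, sample(3:6, 1))
  y <- if (constant) rep(runif(1, 10, 90), j) else runif(j, 5, 95)
  make_stratum(
    y,
    pop = if (with_pop) sample(50:max_pop, j, replace = TRUE) else NULL,
    se = if (with_se) runif(j, 0.5, 3) else NULL,
    type = type,
    order = if (type == "ordered") seq_len(j) else NULL,
    favourable = sample(c(TRUE, FALSE), 1)
  )
}

# long-form value lookup
mval <- function(res, m) {
  v <- res$value[res$measure == m]
  if (length(v) == 0) NA_real_ else v
}

# a small raw template tibble (character cells) for validator tests
raw_template_rows <- function(...) {
  rows <- tibble::tribble(...)
  rows[] <- lapply(rows, as.character)
  for (col in setdiff(healthineq:::TEMPLATE_COLUMNS, names(rows))) {
    rows[[col]] <- NA_character_
  }
  rows
}

# two valid binary strata (the base fixture many validator tests perturb):
# favourable indicator, urban/rural, one setting x two years
base_raw <- function() {
  raw_template_rows(
    ~setting, ~year, ~source, ~indicator_abbr, ~indicator_name, ~dimension,
    ~subgroup, ~estimate, ~se, ~population, ~favourable_indicator,
    ~indicator_scale, ~ordered_dimension, ~subgroup_order,
    ~reference_subgroup,
    "Alandia", 2010, "DHS", "anc", "Antenatal care", "Residence",
    "Rural", 40, 1.2, 600, 1, 100, 0, 0, 0,
    "Alandia", 2010, "DHS", "anc", "Antenatal care", "Residence",
    "Urban", 60, 1.0, 400, 1, 100, 0, 0, 1,
    "Alandia", 2015, "DHS", "anc", "Antenatal care", "Residence",
    "Rural", 50, 1.1, 650, 1, 100, 0, 0, 0,
    "Alandia", 2015, "DHS", "anc", "Antenatal care", "Residence",
    "Urban", 65, 0.9, 350, 1, 100, 0, 0, 1
  )
}

# an ordered education stratum (3 subgroups)
ordered_raw <- function() {
  raw_template_rows(
    ~setting, ~year, ~source, ~indicator_abbr, ~indicator_name, ~dimension,
    ~subgroup, ~estimate, ~se, ~population, ~favourable_indicator,
    ~indicator_scale, ~ordered_dimension, ~subgroup_order,
    ~reference_subgroup,
    "Alandia", 2015, "DHS", "anc", "Antenatal care", "Education",
    "Secondary +", 80, 1.0, 300, 1, 100, 1, 3, 0,
    "Alandia", 2015, "DHS", "anc", "Antenatal care", "Education",
    "No education", 20, 1.5, 300, 1, 100, 1, 1, 0,
    "Alandia", 2015, "DHS", "anc", "Antenatal care", "Education",
    "Primary", 50, 1.2, 400, 1, 100, 1, 2, 0
  )
}
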