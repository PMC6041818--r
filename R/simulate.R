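# Synthetic template datasets with known inequality structure.
#
# The generator emulates the kind of data the template is designed for:
# coverage-style indicators disaggregated by a binary dimension (place of
# residence), an ordered dimension (wealth quintiles) and a non-ordered
# dimension (districts), over several survey years. The inequality
# structure is linear in subgroup rank: the most disadvantaged subgroup
# sits at `base`, the most advantaged at `base + gap`, all subgroups drift
# by `trend` per year, and mean-zero Gaussian noise of sd `noise_sd` is
# added and clipped to [0, scale]. With noise_sd = 0 every summary measure
# has a closed form in the spec parameters (e.g. D = gap).

#' Scenario specification for the synthetic-data generator
#'
#' @param n_settings Number of settings (used when `settings` is `NULL`).
#' @param settings Character vector of setting names.
#' @param years Integer vector of survey years.
#' @param indicators Tibble with columns `abbr`, `name`, `favourable`
#'   (0/1) and `scale`.
#' @param dimensions Tibble with columns `dimension`, `type`
#'   (`"binary"`, `"ordered"` or `"nonordered"`) and `n_subgroups`.
#' @param base Estimate of the most disadvantaged subgroup in the first
#'   year, in indicator units.
#' @param gap Target advantaged-minus-disadvantaged difference per
#'   dimension, in indicator units.
#' @param trend Additive drift per year applied to all subgroups.
#' @param noise_sd Standard deviation of the sampling noise added to each
#'   estimate (0 for noise-free data).
#' @param population_total Total population per stratum.
#' @param population_allocation `"equal"` or `"random"` split of the total
#'   across subgroups.
#' @param missing Named list of switches dropping recommended columns:
#'   `se`, `population`, `setting_average` (each `TRUE` to drop).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `scenario_spec` list.
#' @export
#' @examples
#' spec <- scenario_spec(noise_sd = 0)
#' raw <- generate_dataset(spec)
#' validate_indicator_data(raw)$accepted
scenario_spec <- function(n_settings = 3,
                          settings = NULL,
                          years = c(2005, 2010, 2015),
                          indicators = tibble::tibble(
                            abbr = "anc",
                            name = "Antenatal care coverage",
                            favourable = 1,
                            scale = 100),
                          dimensions = tibble::tibble(
                            dimension = c("Place of residence",
                                          "Wealth quintile",
                                          "Subnational district"),
                            type = c("binary", "ordered", "nonordered"),
                            n_subgroups = c(2L, 5L, 4L)),
                          base = 50,
                          gap = 30,
                          trend = 0.5,
                          noise_sd = 1,
                          population_total = 10000,
                          population_allocation = c("equal", "random"),
                          missing = list(se = FALSE, population = FALSE,
                                         setting_average = FALSE),
                          seed = 2018L) {
  if (is.null(settings)) {
    settings <- paste("Setting", LETTERS[seq_len(n_settings)])
  }
  population_allocation <- match.arg(population_allocation)
  missing <- modifyList(list(se = FALSE, population = FALSE,
                             setting_average = FALSE), missing)
  spec <- structure(
    list(settings = settings, years = sort(as.integer(years)),
         indicators = tibble::as_tibble(indicators),
         dimensions = tibble::as_tibble(dimensions),
         base = base, gap = gap, trend = trend, noise_sd = noise_sd,
         population_total = population_total,
         population_allocation = population_allocation,
         missing = missing, seed = as.integer(seed)),
    class = "scenario_spec")
  check_scenario_spec(spec)
  spec
}

check_scenario_spec <- function(spec) {
  stopifnot(length(spec$settings) >= 1, length(spec$years) >= 1)
  if (any(spec$indicators$scale <= 0)) {
    stop("indicator scale must be positive", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spec$base < 0) stop("base must be >= 0", call. = FALSE)
  bad_j <- spec$dimensions$n_subgroups < 2 |
    (spec$dimensions$type == "binary" & spec$dimensions$n_subgroups != 2) |
    (spec$dimensions$type != "binary" & spec$dimensions$n_subgroups < 3)
  if (any(bad_j)) {
    stop("invalid subgroup counts: binary dimensions need exactly 2 ",
         "subgroups, others more than 2", call. = FALSE)
  }
  if (any(spec$base + spec$gap > spec$indicators$scale)) {
    stop("infeasible spec: base + gap exceeds the indicator scale",
         call. = FALSE)
  }
  invisible(spec)
}

subgroup_names <- function(type, j) {
  switch(type,
         binary = c("Rural", "Urban"),
         ordered = paste("Quintile", seq_len(j)),
         nonordered = paste("District", LETTERS[seq_len(j)]))
}

#' Generate a synthetic template dataset
#'
#' Produces raw template rows (text cells, canonical columns) that pass
#' [validate_indicator_data()] with zero errors; warnings appear only when
#' `missing` switches drop recommended columns. Identical spec and seed
#' give identical output.
#'
#' @param spec A [scenario_spec()].
#' @return A tibble of character columns in canonical template order, with
#'   attribute `"truth"`: a tibble of the noise-free subgroup values
#'   underlying each stratum.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  check_scenario_spec(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  iso3 <- vapply(seq_along(spec$settings), function(i)
    strrep(LETTERS[(i - 1L) %% 26L + 1L], 3), character(1))
  parts <- list()
  truth <- list()
  for (si in seq_along(spec$settings)) {
    for (year in spec$years) {
      for (ii in seq_len(nrow(spec$indicators))) {
        ind <- spec$indicators[ii, ]
        for (di in seq_len(nrow(spec$dimensions))) {
          dim_ <- spec$dimensions[di, ]
          j <- dim_$n_subgroups
          rank_frac <- (seq_len(j) - 1) / (j - 1)
          clean <- spec$base + spec$gap * rank_frac +
            spec$trend * (year - spec$years[1])
          noise <- if (spec$noise_sd > 0) rnorm(j, 0, spec$noise_sd) else 0
          est <- round(pmin(pmax(clean + noise, 0), ind$scale), 6)
          pop <- if (spec$population_allocation == "equal") {
            rep(round(spec$population_total / j), j)
          } else {
            w <- rgamma(j, shape = 5)
            pmax(round(spec$population_total * w / sum(w)), 1)
          }
          p <- pop / sum(pop)
          se <- round(spec$noise_sd / sqrt(j * p), 6)
          avg <- round(sum(p * est), 6)
          ordered <- dim_$type == "ordered"
          parts[[length(parts) + 1L]] <- tibble::tibble(
            setting = spec$settings[si],
            year = year,
            source = "SIM",
            indicator_abbr = ind$abbr,
            indicator_name = ind$name,
            dimension = dim_$dimension,
            subgroup = subgroup_names(dim_$type, j),
            estimate = est,
            se = if (spec$missing$se) NA_real_ else se,
            population = if (spec$missing$population) NA_real_ else pop,
            setting_average = if (spec$missing$setting_average) NA_real_
              else avg,
            iso3 = iso3[si],
            ci_lb = if (spec$missing$se) NA_real_ else
              round(est - 1.96 * se, 6),
            ci_ub = if (spec$missing$se) NA_real_ else
              round(est + 1.96 * se, 6),
            flag = NA_character_,
            favourable_indicator = ind$favourable,
            indicator_scale = ind$scale,
            ordered_dimension = as.numeric(ordered),
            subgroup_order = if (ordered) seq_len(j) else rep(0L, j),
            reference_subgroup = 0
          )
          truth[[length(truth) + 1L]] <- tibble::tibble(
            setting = spec$settings[si], year = year,
            indicator_abbr = ind$abbr, dimension = dim_$dimension,
            subgroup = subgroup_names(dim_$type, j),
            noise_free = pmin(pmax(clean, 0), ind$scale))
        }
      }
    }
  }
  out <- dplyr::bind_rows(parts)
  out[] <- lapply(out, function(x) {
    x <- as.character(x)
    x
  })
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

#' Side table of setting metadata for benchmarking
#'
#' Benchmark comparisons filter settings by tags such as region or income
#' group, which are not template columns; this deterministic side table
#' supplies them for generated scenarios.
#'
#' @param spec A [scenario_spec()].
#' @return A tibble with columns `setting`, `iso3`, `region`,
#'   `income_group`.
#' @export
setting_info <- function(spec) {
  n <- length(spec$settings)
  regions <- c("Region East", "Region West")
  incomes <- c("Low income", "Middle income", "High income")
  tibble::tibble(
    setting = spec$settings,
    iso3 = vapply(seq_len(n), function(i)
      strrep(LETTERS[(i - 1L) %% 26L + 1L], 3), character(1)),
    region = regions[(seq_len(n) - 1L) %% 2L + 1L],
    income_group = incomes[(seq_len(n) - 1L) %% 3L + 1L]
  )
}

#' Write a scenario to disk
#'
#' Writes the generated dataset as CSV and XLSX in canonical template
#' order plus the setting-metadata side table.
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if absent).
#' @param name Base file name.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_scenario <- function(spec, dir, name = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  raw <- generate_dataset(spec)
  paths <- c(
    csv = file.path(dir, paste0(name, ".csv")),
    xlsx = file.path(dir, paste0(name, ".xlsx")),
    settings = file.path(dir, paste0(name, "_settings.csv"))
  )
  write_indicator_data(raw, paths[["csv"]])
  write_indicator_xlsx(raw, paths[["xlsx"]])
  readr::write_csv(setting_info(spec), paths[["settings"]],
                   progress = FALSE)
  invisible(paths)
}
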