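# Summary measures of inequality.
#
# Which measures apply to a stratum is decided by the applicability matrix:
# the dimension type (binary / non-ordered / ordered) crossed with data
# availability (population weights; standard errors). D and R are the only
# measures computable without population; SII and RII additionally require
# standard errors. All degeneracies (zero denominators, non-positive
# estimates for the log-based measures, missing setting average) become
# skips with a reason, never errors.

# reporting conventions: MLD and TI are reported x1000, PAF, RCI, IDIS and
# IDISW x100 of the underlying ratio
SCALE_X1000 <- 1000
SCALE_X100 <- 100

MEASURE_IDS <- c("D", "R", "PAR", "PAF", "SII", "RII", "ACI", "RCI",
                 "BGV", "MDB", "MDM", "IDIS", "IDISW", "MLD", "TI")

#' Summary-measure registry
#'
#' The 15 supported summary measures of inequality with their full names,
#' whether they are absolute (indicator units) or relative (unitless), and
#' their data requirements.
#'
#' @return A tibble with one row per measure.
#' @export
measure_info <- function() {
  tibble::tibble(
    measure = MEASURE_IDS,
    name = c(
      "Difference", "Ratio", "Population attributable risk",
      "Population attributable fraction", "Slope index of inequality",
      "Relative index of inequality", "Absolute concentration index",
      "Relative concentration index", "Between-group variance",
      "Mean difference from best performing subgroup",
      "Mean difference from mean", "Index of disparity",
      "Index of disparity (weighted)", "Mean log deviation", "Theil index"
    ),
    type = c("absolute", "relative", "absolute", "relative", "absolute",
             "relative", "absolute", "relative", "absolute", "absolute",
             "absolute", "relative", "relative", "relative", "relative"),
    needs_population = !MEASURE_IDS %in% c("D", "R"),
    needs_se = MEASURE_IDS %in% c("SII", "RII")
  )
}

#' Applicable summary measures for a stratum
#'
#' Reproduces the applicability matrix. Binary dimensions: D and R, plus
#' PAR and PAF when population is available. Non-ordered dimensions with
#' more than two subgroups: D and R, plus BGV, MDB, MDM, PAR, PAF, IDIS,
#' IDISW, MLD and TI with population. Ordered dimensions: D and R, plus
#' ACI, RCI, PAR and PAF with population, plus SII and RII when both
#' population and standard errors are available on every subgroup. Without
#' population only the unweighted measures D and R can be calculated.
#'
#' @param stratum An `ineq_stratum`.
#' @param has_population,has_se Override the availability flags derived
#'   from the stratum (population / standard error present on every
#'   subgroup).
#' @return Character vector of measure identifiers, in registry order.
#' @export
applicable_measures <- function(stratum,
                                has_population = stratum_has_population(stratum),
                                has_se = stratum_has_se(stratum)) {
  out <- c("D", "R")
  if (has_population) {
    out <- c(out, "PAR", "PAF")
    if (stratum$dimension_type == "nonordered") {
      out <- c(out, "BGV", "MDB", "MDM", "IDIS", "IDISW", "MLD", "TI")
    } else if (stratum$dimension_type == "ordered") {
      out <- c(out, "ACI", "RCI")
      if (has_se) out <- c(out, "SII", "RII")
    }
  }
  MEASURE_IDS[MEASURE_IDS %in% out]
}

#' Setting average for a stratum
#'
#' The overall indicator level mu. A reported `setting_average` in the
#' template takes precedence as the authoritative figure; otherwise the
#' population-weighted mean of the subgroup estimates is used when every
#' subgroup has a population; otherwise the average is unavailable
#' (`NA`).
#'
#' @param stratum An `ineq_stratum`.
#' @return A single numeric value, `NA` when unavailable.
#' @export
setting_average <- function(stratum) {
  if (!is.na(stratum$setting_average_provided)) {
    return(stratum$setting_average_provided)
  }
  s <- stratum$subgroups
  if (all(!is.na(s$population))) {
    return(sum(s$population * s$estimate) / sum(s$population))
  }
  NA_real_
}

#' Population rank midpoints
#'
#' For an ordered stratum with subgroups sorted most disadvantaged first,
#' the rank midpoint of subgroup j is its cumulative population share up to
#' and including j, minus half its own share — the abscissa used by the
#' concentration indices and the slope/relative index of inequality. With
#' equal populations and J subgroups this is (2j - 1) / (2J).
#'
#' @param stratum An `ineq_stratum` with populations on every subgroup.
#' @return Numeric vector of midpoints in (0, 1), or `NULL` when any
#'   population is missing.
#' @export
rank_midpoints <- function(stratum) {
  pop <- stratum$subgroups$population
  if (anyNA(pop)) return(NULL)
  p <- pop / sum(pop)
  cumsum(p) - p / 2
}

# ---- result plumbing --------------------------------------------------------

measure_row <- function(measure, value, weighted, notes = character()) {
  tibble::tibble(measure = measure, value = value, weighted = weighted,
                 notes = paste(notes, collapse = "; "))
}

skip_row <- function(measure, reason) {
  tibble::tibble(measure = measure, reason = reason)
}

empty_results <- function() {
  tibble::tibble(measure = character(), value = numeric(),
                 weighted = logical(), notes = character())
}

finish <- function(results, skipped) {
  results <- if (length(results)) dplyr::bind_rows(results) else empty_results()
  attr(results, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    skip_row(character(), character())
  results
}

#' Skipped-measure log
#'
#' Companion log of measures that were not computed, with the reason
#' (inapplicability or a data degeneracy), attached by [compute_stratum()]
#' and [compute_measures()].
#'
#' @param x A result tibble from [compute_stratum()] or
#'   [compute_measures()].
#' @return A tibble with at least `measure` and `reason`.
#' @export
skipped_measures <- function(x) attr(x, "skipped")

# deterministic extremes: ties broken alphabetically by subgroup name
pick_extreme <- function(s, largest) {
  o <- if (largest) order(-s$estimate, s$subgroup) else
    order(s$estimate, s$subgroup)
  s[o[1], ]
}

# the two subgroups D and R compare, plus a descriptive note
comparison_pair <- function(stratum) {
  s <- stratum$subgroups
  if (stratum$dimension_type == "ordered") {
    dis <- s[1, ]                 # sorted most disadvantaged first
    adv <- s[nrow(s), ]
    if (stratum$favourable) {
      list(top = adv, bottom = dis,
           note = paste0("advantaged '", adv$subgroup,
                         "' vs disadvantaged '", dis$subgroup, "'"))
    } else {
      list(top = dis, bottom = adv,
           note = paste0("disadvantaged '", dis$subgroup,
                         "' vs advantaged '", adv$subgroup, "'"))
    }
  } else if (any(s$reference)) {
    ref <- s[s$reference, ][1, ]
    others <- s[s$subgroup != ref$subgroup, ]
    o <- order(-abs(others$estimate - ref$estimate), others$subgroup)
    ext <- others[o[1], ]
    list(top = ext, bottom = ref,
         note = paste0("extreme '", ext$subgroup, "' vs reference '",
                       ref$subgroup, "'"))
  } else {
    mx <- pick_extreme(s, TRUE)
    mn <- pick_extreme(s, FALSE)
    list(top = mx, bottom = mn,
         note = paste0("max '", mx$subgroup, "' vs min '", mn$subgroup, "'"))
  }
}

# ---- individual measures ----------------------------------------------------

#' Difference and ratio
#'
#' The simplest pairwise measures. For an ordered stratum they compare the
#' most advantaged and most disadvantaged subgroups, oriented so that a
#' positive difference (ratio above 1) indicates inequality burdening the
#' disadvantaged: advantaged minus disadvantaged for favourable indicators,
#' the reverse for adverse ones. For binary and non-ordered strata without
#' a designated reference subgroup they compare the maximum and minimum
#' estimates; with a reference subgroup r, they compare r with the subgroup
#' farthest from it (extreme-vs-reference; the note records the pair). The
#' ratio is skipped with reason `zero_denominator` when its denominator is
#' zero.
#'
#' @param stratum An `ineq_stratum`.
#' @return A result tibble (see [compute_stratum()]) with the skip log in
#'   attribute `"skipped"`.
#' @export
compute_d <- function(stratum) {
  pr <- comparison_pair(stratum)
  finish(list(measure_row("D", pr$top$estimate - pr$bottom$estimate,
                          weighted = FALSE, notes = pr$note)), list())
}

#' @rdname compute_d
#' @export
compute_r <- function(stratum) {
  pr <- comparison_pair(stratum)
  if (pr$bottom$estimate == 0) {
    return(finish(list(), list(skip_row("R", "zero_denominator"))))
  }
  finish(list(measure_row("R", pr$top$estimate / pr$bottom$estimate,
                          weighted = FALSE, notes = pr$note)), list())
}

#' Population attributable risk and fraction
#'
#' PAR is the improvement in the setting average mu that would be achieved
#' if every subgroup matched the reference subgroup: the most advantaged
#' subgroup for ordered dimensions, otherwise the designated reference
#' subgroup if one exists, else the best-performing subgroup (highest
#' estimate for favourable indicators, lowest for adverse). PAR is
#' truncated to 0 (with a note) when its sign is contrary to improvement
#' (negative for favourable indicators, positive for adverse). PAF is the
#' percentage form, 100 * PAR / mu.
#'
#' @param stratum An `ineq_stratum` with populations (or a reported
#'   setting average).
#' @param mu The setting average; defaults to [setting_average()].
#' @return A result tibble with skip log attribute.
#' @export
compute_par_paf <- function(stratum, mu = setting_average(stratum)) {
  if (is.na(mu)) {
    return(finish(list(), list(skip_row("PAR", "no_setting_average"),
                               skip_row("PAF", "no_setting_average"))))
  }
  s <- stratum$subgroups
  notes <- character()
  if (stratum$dimension_type == "ordered") {
    ref <- s[nrow(s), ]
    notes <- paste0("reference: most advantaged '", ref$subgroup, "'")
  } else if (any(s$reference)) {
    ref <- s[s$reference, ][1, ]
    notes <- paste0("reference: designated '", ref$subgroup, "'")
  } else {
    ref <- pick_extreme(s, largest = stratum$favourable)
    notes <- paste0("reference: best performing '", ref$subgroup, "'")
  }
  par <- ref$estimate - mu
  contrary <- (stratum$favourable && par < 0) || (!stratum$favourable && par > 0)
  if (contrary) {
    par <- 0
    notes <- c(notes, "truncated to 0 (reference no better than average)")
  }
  results <- list(measure_row("PAR", par, weighted = TRUE, notes = notes))
  skipped <- list()
  if (mu > 0) {
    results <- c(results, list(
      measure_row("PAF", SCALE_X100 * par / mu, weighted = TRUE,
                  notes = notes)))
  } else {
    skipped <- list(skip_row("PAF", "nonpositive_setting_average"))
  }
  finish(results, skipped)
}

#' Between-group variance
#'
#' BGV = sum over subgroups of p_j (y_j - mu)^2, with p_j the population
#' share: the population-weighted variance of the subgroup estimates around
#' the setting average, in squared indicator units. Used for non-ordered
#' dimensions with more than two subgroups.
#'
#' @inheritParams compute_par_paf
#' @return A result tibble with skip log attribute.
#' @export
compute_bgv <- function(stratum, mu = setting_average(stratum)) {
  s <- stratum$subgroups
  if (anyNA(s$population)) {
    return(finish(list(), list(skip_row("BGV", "missing_population"))))
  }
  if (is.na(mu)) {
    return(finish(list(), list(skip_row("BGV", "no_setting_average"))))
  }
  p <- s$population / sum(s$population)
  finish(list(measure_row("BGV", sum(p * (s$estimate - mu)^2),
                          weighted = TRUE)), list())
}

#' Mean difference from best performing subgroup and from the mean
#'
#' MDB = sum p_j |y_j - y_best| with the best-performing subgroup taken as
#' the highest estimate for favourable indicators and the lowest for
#' adverse; MDM = sum p_j |y_j - mu|. Both are absolute dispersion measures
#' for non-ordered dimensions.
#'
#' @inheritParams compute_par_paf
#' @return A result tibble with skip log attribute.
#' @export
compute_mdb_mdm <- function(stratum, mu = setting_average(stratum)) {
  s <- stratum$subgroups
  if (anyNA(s$population)) {
    return(finish(list(), list(skip_row("MDB", "missing_population"),
                               skip_row("MDM", "missing_population"))))
  }
  p <- s$population / sum(s$population)
  best <- pick_extreme(s, largest = stratum$favourable)
  results <- list(
    measure_row("MDB", sum(p * abs(s$estimate - best$estimate)),
                weighted = TRUE,
                notes = paste0("best performing '", best$subgroup, "'")))
  skipped <- list()
  if (!is.na(mu)) {
    results <- c(results, list(
      measure_row("MDM", sum(p * abs(s$estimate - mu)), weighted = TRUE)))
  } else {
    skipped <- list(skip_row("MDM", "no_setting_average"))
  }
  finish(results, skipped)
}

#' Index of disparity, unweighted and weighted
#'
#' Relative dispersion around the setting average, reported as a
#' percentage: IDIS = 100 * (mean over subgroups of |y_j - mu|) / mu and
#' IDISW = 100 * (sum p_j |y_j - mu|) / mu.
#'
#' @inheritParams compute_par_paf
#' @return A result tibble with skip log attribute.
#' @export
compute_idis_idisw <- function(stratum, mu = setting_average(stratum)) {
  s <- stratum$subgroups
  if (is.na(mu)) {
    return(finish(list(), list(skip_row("IDIS", "no_setting_average"),
                               skip_row("IDISW", "no_setting_average"))))
  }
  if (mu <= 0) {
    return(finish(list(), list(skip_row("IDIS", "nonpositive_setting_average"),
                               skip_row("IDISW", "nonpositive_setting_average"))))
  }
  results <- list(
    measure_row("IDIS", SCALE_X100 * mean(abs(s$estimate - mu)) / mu,
                weighted = FALSE))
  skipped <- list()
  if (!anyNA(s$population)) {
    p <- s$population / sum(s$population)
    results <- c(results, list(
      measure_row("IDISW", SCALE_X100 * sum(p * abs(s$estimate - mu)) / mu,
                  weighted = TRUE)))
  } else {
    skipped <- list(skip_row("IDISW", "missing_population"))
  }
  finish(results, skipped)
}

#' Mean log deviation and Theil index
#'
#' Entropy-family relative measures for non-ordered dimensions, reported
#' x1000: MLD = 1000 * sum p_j ln(mu / y_j) and
#' TI = 1000 * sum p_j (y_j / mu) ln(y_j / mu). Both require strictly
#' positive subgroup estimates and setting average; a non-positive estimate
#' skips them with reason `nonpositive_estimate`.
#'
#' @inheritParams compute_par_paf
#' @return A result tibble with skip log attribute.
#' @export
compute_mld_theil <- function(stratum, mu = setting_average(stratum)) {
  s <- stratum$subgroups
  if (anyNA(s$population)) {
    return(finish(list(), list(skip_row("MLD", "missing_population"),
                               skip_row("TI", "missing_population"))))
  }
  if (is.na(mu) || mu <= 0) {
    return(finish(list(), list(skip_row("MLD", "nonpositive_setting_average"),
                               skip_row("TI", "nonpositive_setting_average"))))
  }
  if (any(s$estimate <= 0)) {
    return(finish(list(), list(skip_row("MLD", "nonpositive_estimate"),
                               skip_row("TI", "nonpositive_estimate"))))
  }
  p <- s$population / sum(s$population)
  finish(list(
    measure_row("MLD", SCALE_X1000 * sum(p * log(mu / s$estimate)),
                weighted = TRUE),
    measure_row("TI", SCALE_X1000 * sum(p * (s$estimate / mu) *
                                          log(s$estimate / mu)),
                weighted = TRUE)
  ), list())
}

#' Absolute and relative concentration index
#'
#' Gradient measures for ordered dimensions. With rank midpoints X_j from
#' [rank_midpoints()] (most disadvantaged first),
#' ACI = sum p_j (2 X_j - 1) y_j; RCI = 100 * ACI / mu. ACI equals the
#' individual-level concentration index computed on a population expanded
#' person by person.
#'
#' @inheritParams compute_par_paf
#' @return A result tibble with skip log attribute.
#' @export
compute_aci_rci <- function(stratum, mu = setting_average(stratum)) {
  s <- stratum$subgroups
  x <- rank_midpoints(stratum)
  if (is.null(x)) {
    return(finish(list(), list(skip_row("ACI", "missing_population"),
                               skip_row("RCI", "missing_population"))))
  }
  p <- s$population / sum(s$population)
  aci <- sum(p * (2 * x - 1) * s$estimate)
  results <- list(measure_row("ACI", aci, weighted = TRUE))
  skipped <- list()
  if (!is.na(mu) && mu > 0) {
    results <- c(results, list(
      measure_row("RCI", SCALE_X100 * aci / mu, weighted = TRUE)))
  } else {
    skipped <- list(skip_row("RCI", "nonpositive_setting_average"))
  }
  finish(results, skipped)
}

#' Slope and relative index of inequality
#'
#' Regression-based gradient measures for ordered dimensions: subgroup
#' estimates are regressed on their population rank midpoints by weighted
#' least squares with population-share weights. SII is the fitted change
#' across the full rank scale, yhat(1) - yhat(0); RII is the ratio
#' yhat(1) / yhat(0). Both require population and standard errors on every
#' subgroup (the standard errors gate applicability; the point estimate is
#' the natural-scale WLS fit). RII is skipped when the fitted value at rank
#' 0 is non-positive. For adverse indicators the note records that a
#' positive SII means the burden falls on the advantaged end of the
#' ranking.
#'
#' @param stratum An `ineq_stratum`.
#' @return A result tibble with skip log attribute.
#' @export
compute_sii_rii <- function(stratum) {
  s <- stratum$subgroups
  x <- rank_midpoints(stratum)
  if (is.null(x) || anyNA(s$se)) {
    return(finish(list(), list(skip_row("SII", "missing_population_or_se"),
                               skip_row("RII", "missing_population_or_se"))))
  }
  p <- s$population / sum(s$population)
  fit <- stats::lm(s$estimate ~ x, weights = p)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  notes <- if (!stratum$favourable)
    "adverse indicator: positive SII means higher burden at the advantaged end"
  else character()
  results <- list(measure_row("SII", b, weighted = TRUE, notes = notes))
  skipped <- list()
  if (a > 0) {
    results <- c(results, list(
      measure_row("RII", (a + b) / a, weighted = TRUE, notes = notes)))
  } else {
    skipped <- list(skip_row("RII", "nonpositive_rank0_fit"))
  }
  finish(results, skipped)
}

# ---- orchestration ----------------------------------------------------------

#' Compute all applicable summary measures for one stratum
#'
#' Determines the applicable measures via [applicable_measures()], computes
#' each, and returns the results in long form. Measures that are not
#' applicable, or that hit a data degeneracy, are absent from the results
#' and listed with a reason in the skip log ([skipped_measures()]).
#' Degenerate data never throw.
#'
#' @param stratum An `ineq_stratum`.
#' @param measures Optional character vector restricting which measures to
#'   compute (identifiers from [measure_info()]).
#' @return A tibble with columns `measure`, `value`, `weighted`, `notes`,
#'   and the skip log in attribute `"skipped"`.
#' @export
#' @examples
#' d <- validate_indicator_data(generate_dataset(scenario_spec()))$dataset
#' compute_stratum(stratify(d)[[1]])
compute_stratum <- function(stratum, measures = NULL) {
  stopifnot(inherits(stratum, "ineq_stratum"))
  applicable <- applicable_measures(stratum)
  wanted <- if (is.null(measures)) MEASURE_IDS else {
    bad <- setdiff(measures, MEASURE_IDS)
    if (length(bad) > 0 || length(measures) == 0) {
      stop("unknown or empty measure selection",
           if (length(bad)) paste0(" (", paste(bad, collapse = ", "), ")"),
           "; valid measures: ", paste(MEASURE_IDS, collapse = ", "),
           call. = FALSE)
    }
    measures
  }
  run <- intersect(applicable, wanted)
  mu <- setting_average(stratum)

  parts <- list()
  skipped <- list(skip_row(setdiff(wanted, applicable), "not_applicable"))
  add <- function(res) {
    parts[[length(parts) + 1L]] <<- res
    skipped[[length(skipped) + 1L]] <<- attr(res, "skipped")
  }
  if ("D" %in% run) add(compute_d(stratum))
  if ("R" %in% run) add(compute_r(stratum))
  if (any(c("PAR", "PAF") %in% run)) add(compute_par_paf(stratum, mu))
  if ("BGV" %in% run) add(compute_bgv(stratum, mu))
  if (any(c("MDB", "MDM") %in% run)) add(compute_mdb_mdm(stratum, mu))
  if (any(c("IDIS", "IDISW") %in% run)) add(compute_idis_idisw(stratum, mu))
  if (any(c("MLD", "TI") %in% run)) add(compute_mld_theil(stratum, mu))
  if (any(c("ACI", "RCI") %in% run)) add(compute_aci_rci(stratum, mu))
  if (any(c("SII", "RII") %in% run)) add(compute_sii_rii(stratum))

  results <- dplyr::bind_rows(c(list(empty_results()), parts))
  results <- results[results$measure %in% run, ]
  results <- results[order(match(results$measure, MEASURE_IDS)), ]
  skip_log <- dplyr::bind_rows(skipped)
  skip_log <- skip_log[skip_log$measure %in% wanted, ]
  attr(results, "skipped") <- skip_log
  results
}

#' Compute summary measures for every stratum of a dataset
#'
#' Applies [compute_stratum()] across all strata and returns one long
#' table, mirroring the summary-measure download format.
#'
#' @param dataset An [ineq_data] object.
#' @param measures Optional measure subset, as in [compute_stratum()].
#' @return A tibble with the stratum key columns (`setting`, `year`,
#'   `source`, `indicator_abbr`, `dimension`) plus `measure`, `value`,
#'   `weighted`, `notes`; skip log (with key columns) in attribute
#'   `"skipped"`.
#' @export
compute_measures <- function(dataset, measures = NULL) {
  strata <- stratify(dataset)
  parts <- lapply(strata, function(st) {
    res <- compute_stratum(st, measures)
    key <- tibble::tibble(setting = st$setting, year = st$year,
                          source = st$source,
                          indicator_abbr = st$indicator_abbr,
                          dimension = st$dimension)
    list(results = dplyr::bind_cols(key[rep(1, nrow(res)), ], res),
         skipped = dplyr::bind_cols(
           key[rep(1, nrow(skipped_measures(res))), ],
           skipped_measures(res)))
  })
  out <- dplyr::bind_rows(lapply(parts, `[[`, "results"))
  attr(out, "skipped") <- dplyr::bind_rows(lapply(parts, `[[`, "skipped"))
  out
}

#' Write summary-measure results as CSV
#'
#' @param results Output of [compute_measures()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measures <- function(results, path) {
  readr::write_csv(tibble::as_tibble(results), path, na = "",
                   progress = FALSE)
  invisible(path)
}
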