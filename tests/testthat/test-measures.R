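# Unit oracles for each summary measure and the applicability gating.

test_that("setting average: provided value wins, else population-weighted mean", {
  expect_equal(setting_average(make_stratum(c(40, 60), pop = c(50, 50))), 50)
  expect_equal(setting_average(make_stratum(c(20, 80), pop = c(30, 70))), 62)
  expect_equal(setting_average(make_stratum(c(40, 60), pop = c(50, 50),
                                            avg = 55)), 55)
  expect_true(is.na(setting_average(make_stratum(c(40, 60)))))
})

test_that("rank midpoints are cumulative shares minus half-widths", {
  expect_equal(rank_midpoints(make_stratum(c(1, 2), pop = c(50, 50),
                                           type = "ordered")),
               c(0.25, 0.75))
  expect_equal(rank_midpoints(make_stratum(c(1, 2, 3), pop = c(20, 30, 50),
                                           type = "ordered")),
               c(0.10, 0.35, 0.75))
  for (j in c(3, 5, 8)) {
    expect_equal(rank_midpoints(make_stratum(runif(j), pop = rep(7, j),
                                             type = "ordered")),
                 (2 * seq_len(j) - 1) / (2 * j))
  }
  expect_null(rank_midpoints(make_stratum(c(1, 2, 3), type = "ordered")))
})

test_that("difference and ratio compare the right subgroups", {
  ord <- make_stratum(c(20, 50, 80), type = "ordered")
  expect_equal(mval(compute_d(ord), "D"), 60)
  expect_equal(mval(compute_r(ord), "R"), 4)

  adverse <- make_stratum(c(30, 20, 10), type = "ordered",
                          favourable = FALSE)
  expect_equal(mval(compute_d(adverse), "D"), 20)
  expect_equal(mval(compute_r(adverse), "R"), 3)

  flat <- make_stratum(c(55, 55, 55))
  expect_equal(mval(compute_d(flat), "D"), 0)
  expect_equal(mval(compute_r(flat), "R"), 1)

  # non-ordered with a zero minimum: D defined, R skipped
  zero <- make_stratum(c(0, 30, 60))
  expect_equal(mval(compute_d(zero), "D"), 60)
  r <- compute_r(zero)
  expect_equal(nrow(r), 0)
  expect_equal(skipped_measures(r)$reason, "zero_denominator")
})

test_that("a designated reference subgroup switches D/R to extreme-vs-reference", {
  st <- make_stratum(c(50, 20, 90), names = c("Capital", "North", "South"),
                     reference = "Capital")
  d <- compute_d(st)
  expect_equal(mval(d, "D"), 90 - 50)  # South is farthest from Capital
  expect_match(d$notes, "reference 'Capital'")
  expect_equal(mval(compute_r(st), "R"), 90 / 50)
})

test_that("PAR and PAF use the proper reference and truncate on contrary sign", {
  st <- make_stratum(c(40, 60), pop = c(50, 50))
  res <- compute_par_paf(st)
  expect_equal(mval(res, "PAR"), 10)
  expect_equal(mval(res, "PAF"), 20)

  adverse <- make_stratum(c(30, 20, 10), pop = rep(1, 3), type = "ordered",
                          favourable = FALSE)
  res2 <- compute_par_paf(adverse)
  expect_equal(mval(res2, "PAR"), -10)
  expect_equal(mval(res2, "PAF"), -50)

  # most-advantaged subgroup below the average: attainable gain is 0
  trunc <- make_stratum(c(50, 80, 40), pop = rep(1, 3), type = "ordered")
  res3 <- compute_par_paf(trunc)
  expect_equal(mval(res3, "PAR"), 0)
  expect_match(res3$notes[res3$measure == "PAR"], "truncated")
})

test_that("BGV is the population-weighted variance around the average", {
  expect_equal(mval(compute_bgv(make_stratum(c(40, 60), pop = c(50, 50))),
                    "BGV"), 100)
  expect_equal(mval(compute_bgv(make_stratum(c(20, 80), pop = c(30, 70))),
                    "BGV"), 756)
  expect_equal(mval(compute_bgv(make_stratum(rep(33, 4), pop = rep(5, 4))),
                    "BGV"), 0)
})

test_that("MDB and MDM are weighted mean absolute differences", {
  st <- make_stratum(c(40, 60), pop = c(50, 50))
  res <- compute_mdb_mdm(st)
  expect_equal(mval(res, "MDB"), 10)
  expect_equal(mval(res, "MDM"), 10)

  adv <- make_stratum(c(40, 60), pop = c(50, 50), favourable = FALSE)
  expect_equal(mval(compute_mdb_mdm(adv), "MDB"), 10)  # best = 40

  flat <- make_stratum(rep(70, 3), pop = rep(2, 3))
  res3 <- compute_mdb_mdm(flat)
  expect_equal(mval(res3, "MDB"), 0)
  expect_equal(mval(res3, "MDM"), 0)
})

test_that("IDIS and IDISW are percentage mean deviations from the average", {
  st <- make_stratum(c(40, 60), pop = c(50, 50))
  res <- compute_idis_idisw(st)
  expect_equal(mval(res, "IDIS"), 20)
  expect_equal(mval(res, "IDISW"), 20)

  st2 <- make_stratum(c(20, 80), pop = c(30, 70))
  expect_equal(mval(compute_idis_idisw(st2), "IDISW"),
               100 * (0.3 * 42 + 0.7 * 18) / 62)

  flat <- make_stratum(rep(12, 5), pop = rep(9, 5))
  res3 <- compute_idis_idisw(flat)
  expect_equal(mval(res3, "IDIS"), 0)
  expect_equal(mval(res3, "IDISW"), 0)
})

test_that("MLD and Theil match their closed forms (x1000 reporting scale)", {
  st <- make_stratum(c(25, 75), pop = c(50, 50))
  res <- compute_mld_theil(st)
  expect_equal(mval(res, "MLD"),
               1000 * (0.5 * log(50 / 25) + 0.5 * log(50 / 75)))
  expect_equal(mval(res, "TI"),
               1000 * (0.5 * (25 / 50) * log(25 / 50) +
                         0.5 * (75 / 50) * log(75 / 50)))

  flat <- make_stratum(rep(40, 3), pop = rep(1, 3))
  expect_equal(mval(compute_mld_theil(flat), "MLD"), 0)
  expect_equal(mval(compute_mld_theil(flat), "TI"), 0)

  zero <- make_stratum(c(0, 30, 60), pop = rep(1, 3))
  res3 <- compute_mld_theil(zero)
  expect_equal(nrow(res3), 0)
  expect_setequal(skipped_measures(res3)$reason, "nonpositive_estimate")
})

test_that("ACI and RCI match the concentration-curve formula", {
  st <- make_stratum(c(40, 60), pop = c(50, 50), type = "ordered",
                     order = 1:2)
  res <- compute_aci_rci(st)
  expect_equal(mval(res, "ACI"), 5)
  expect_equal(mval(res, "RCI"), 10)

  flat <- make_stratum(rep(30, 4), pop = c(10, 20, 30, 40),
                       type = "ordered")
  expect_equal(mval(compute_aci_rci(flat), "ACI"), 0)
})

test_that("SII and RII come from weighted least squares on rank midpoints", {
  st <- make_stratum(c(40, 60), pop = c(50, 50), se = c(1, 1),
                     type = "ordered", order = 1:2)
  res <- compute_sii_rii(st)
  expect_equal(mval(res, "SII"), 40)
  expect_equal(mval(res, "RII"), 70 / 30)

  col <- make_stratum(c(20, 50, 80), pop = rep(10, 3), se = rep(1, 3),
                      type = "ordered")
  res2 <- compute_sii_rii(col)
  expect_equal(mval(res2, "SII"), 90)
  expect_equal(mval(res2, "RII"), 19)

  flat <- make_stratum(rep(45, 3), pop = rep(10, 3), se = rep(1, 3),
                       type = "ordered")
  res3 <- compute_sii_rii(flat)
  expect_equal(mval(res3, "SII"), 0)
  expect_equal(mval(res3, "RII"), 1)
})

test_that("the applicability matrix is reproduced exactly", {
  bin <- make_stratum(c(40, 60), pop = c(1, 1), se = c(1, 1))
  expect_setequal(applicable_measures(bin), c("D", "R", "PAR", "PAF"))
  expect_setequal(applicable_measures(bin, has_population = FALSE),
                  c("D", "R"))

  non <- make_stratum(runif(4, 20, 80), pop = rep(1, 4), se = rep(1, 4))
  expect_setequal(applicable_measures(non),
                  c("D", "R", "PAR", "PAF", "BGV", "MDB", "MDM", "IDIS",
                    "IDISW", "MLD", "TI"))

  ord <- make_stratum(runif(4, 20, 80), pop = rep(1, 4), se = rep(1, 4),
                      type = "ordered")
  expect_setequal(applicable_measures(ord),
                  c("D", "R", "PAR", "PAF", "ACI", "RCI", "SII", "RII"))
  expect_setequal(applicable_measures(ord, has_se = FALSE),
                  c("D", "R", "PAR", "PAF", "ACI", "RCI"))
  expect_setequal(applicable_measures(ord, has_population = FALSE),
                  c("D", "R"))

  # union over the three full-data types covers all 15 measures;
  # D and R are the only population-free ones, SII/RII the only se-gated
  all_measures <- union(applicable_measures(bin),
                        union(applicable_measures(non),
                              applicable_measures(ord)))
  expect_length(all_measures, 15)
  info <- measure_info()
  expect_setequal(info$measure[!info$needs_population], c("D", "R"))
  expect_setequal(info$measure[info$needs_se], c("SII", "RII"))
})

test_that("compute_stratum returns exactly the applicable measures with a skip log", {
  ord <- make_stratum(c(20, 40, 60, 80), pop = rep(10, 4), se = rep(1, 4),
                      type = "ordered")
  expect_length(compute_stratum(ord)$measure, 8)

  non <- make_stratum(c(20, 40, 60, 80), pop = rep(10, 4), se = rep(1, 4))
  expect_length(compute_stratum(non)$measure, 11)

  bare <- make_stratum(c(20, 40, 60, 80))
  res <- compute_stratum(bare)
  expect_setequal(res$measure, c("D", "R"))
  sk <- skipped_measures(res)
  expect_true(all(setdiff(healthineq:::MEASURE_IDS, c("D", "R")) %in%
                    sk$measure))
  expect_true(all(sk$reason == "not_applicable"))

  # explicit subset: inapplicable requests end up in the log, not errors
  res2 <- compute_stratum(bare, measures = c("D", "BGV"))
  expect_equal(res2$measure, "D")
  expect_equal(skipped_measures(res2),
               tibble::tibble(measure = "BGV", reason = "not_applicable"))
  expect_error(compute_stratum(bare, measures = "XYZ"), "valid measures")
  expect_error(compute_stratum(bare, measures = character()),
               "valid measures")
})

test_that("compute_measures yields the long download format across strata", {
  rep <- validate_indicator_data(dplyr::bind_rows(base_raw(),
                                                  ordered_raw()))
  res <- compute_measures(rep$dataset)
  expect_true(all(c("setting", "year", "source", "indicator_abbr",
                    "dimension", "measure", "value", "weighted",
                    "notes") %in% names(res)))
  # binary strata have no setting_average and no population? they do have
  # population, so 4 measures each; ordered stratum has pop+se: 8
  counts <- table(paste(res$year, res$dimension))
  expect_equal(unname(counts[["2015 Education"]]), 8)
  expect_equal(unname(counts[["2010 Residence"]]), 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measures(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(res))
})
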